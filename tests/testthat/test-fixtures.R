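ml <- get_primer("mlCOIintF")
xt <- get_primer("mlCOIintF-XT")

test_that("conserved fill matches both forward primers at every position", {
  fill <- conserved_fill_bases()
  expect_length(fill, 26)
  mlc <- strsplit(ml$sequence, "")[[1]]
  xtc <- strsplit(xt$sequence, "")[[1]]
  expect_true(all(bases_compatible(mlc, fill)))
  expect_true(all(bases_compatible(xtc, fill)))
})

test_that("every printed mismatch pair in the three transcription tables reproduces", {
  for (ds in c("oithona_similis", "appendicularia", "thaliacea")) {
    tab <- fixture_table(ds)
    regs <- fixture_regions(ds)
    got_ml <- vapply(regs, function(r) profile_mismatches(ml, r)$total, integer(1))
    got_xt <- vapply(regs, function(r) profile_mismatches(xt, r)$total, integer(1))
    expect_identical(got_ml, as.integer(tab$printed_mlCOIintF), info = ds)
    expect_identical(got_xt, as.integer(tab$printed_LerayXT), info = ds)
    # the more degenerate primer never has more mismatches
    expect_true(all(got_xt <= got_ml), info = ds)
  }
})

test_that("fixture shapes match their documented sizes", {
  expect_identical(nrow(fixture_table("oithona_similis")), 14L)
  expect_identical(sum(fixture_table("oithona_similis")$n), 247L)
  expect_length(fixture_regions("oithona_similis", with_multiplicity = TRUE), 247)

  app <- fixture_table("appendicularia")
  expect_identical(nrow(app), 21L)
  expect_identical(length(unique(app$species)), 14L)
  expect_identical(sum(app$polyt == "yes"), 9L)
  expect_identical(length(unique(app$species[app$polyt == "yes"])), 7L)

  tha <- fixture_table("thaliacea")
  expect_identical(nrow(tha), 15L)
  expect_identical(length(unique(tha$species)), 12L)

  expect_error(fixture_table("oithona_nana_partial"), "reserved")
})

test_that("XT superset monotonicity holds across all fixture regions", {
  all_regs <- c(fixture_regions("oithona_similis", with_multiplicity = TRUE),
                fixture_regions("appendicularia"),
                fixture_regions("thaliacea"))
  expect_length(all_regs, 283)
  for (r in all_regs) {
    expect_lte(profile_mismatches(xt, r)$total, profile_mismatches(ml, r)$total)
  }
})

test_that("profiles are invariant to the conserved-fill choice", {
  # any fill compatible with both primers gives identical profiles
  fill_default <- conserved_fill_bases()
  fill_alt <- vapply(1:26, function(p) {
    both <- intersect(allowed_bases(substr(ml$sequence, p, p)),
                      allowed_bases(substr(xt$sequence, p, p)))
    both[length(both)] # lexicographically largest instead of smallest
  }, character(1))
  expect_false(identical(fill_default, fill_alt)) # the choice is real
  for (ds in c("oithona_similis", "appendicularia", "thaliacea")) {
    r1 <- fixture_regions(ds)
    r2 <- fixture_regions(ds, fill = fill_alt)
    for (i in seq_along(r1)) {
      expect_identical(profile_mismatches(ml, r1[[i]])$mismatch_positions,
                       profile_mismatches(ml, r2[[i]])$mismatch_positions)
      expect_identical(profile_mismatches(xt, r1[[i]])$mismatch_positions,
                       profile_mismatches(xt, r2[[i]])$mismatch_positions)
    }
  }
})

test_that("random_region plants exactly k mismatches where asked", {
  set.seed(83)
  for (i in 1:25) {
    k <- sample(0:6, 1)
    term <- k > 0 && sample(c(TRUE, FALSE), 1)
    reg <- random_region(ml, k, terminal = term)
    prof <- profile_mismatches(ml, reg)
    expect_identical(prof$total, k)
    if (term) expect_true(prof$terminal3_hit)
  }
  expect_identical(profile_mismatches(ml, random_region(ml, 0))$total, 0L)
  # k = 4 with a terminal hit is classified as likely failure
  r <- random_region(ml, 4, terminal = TRUE, seed = 4)
  expect_identical(as.character(classify_risk(profile_mismatches(ml, r))$level),
                   "failure_likely")
  # jgHCO2198 has three inosine positions, which can never mismatch
  expect_error(random_region(get_primer("jgHCO2198"), 26), "non-universal")
})

test_that("synthetic records are deterministic and recover planted sites", {
  regs <- fixture_regions("oithona_similis")
  cfg <- synthetic_config(seed = 42)
  s1 <- synthesize_fasta(regs, cfg)
  s2 <- synthesize_fasta(regs, cfg)
  expect_identical(s1, s2)
  s3 <- synthesize_fasta(regs, synthetic_config(seed = 43))
  expect_false(identical(as.character(s1), as.character(s3)))

  meta <- attr(s1, "meta")
  for (i in seq_along(s1)) {
    loc <- locate_binding_site(s1[[i]], ml)
    expect_identical(attr(loc, "mismatches"),
                     profile_mismatches(ml, regs[[i]])$total)
    expect_identical(loc$start, meta$fwd_start[i])
  }
  # the planted reverse target is a perfect match for its primer
  jg <- get_primer("jgHCO2198")
  for (i in seq_len(3)) {
    expect_identical(profile_reverse(jg, s1[[i]])$total, 0L)
  }
})

test_that("fasta round trip preserves synthetic records", {
  regs <- fixture_regions("thaliacea")[1:4]
  s <- synthesize_fasta(regs, synthetic_config(seed = 7))
  f <- tempfile(fileext = ".fasta")
  write_fasta(s, f)
  back <- read_templates(f)
  expect_identical(unname(back), unname(as.character(s)))
  expect_identical(names(back), names(s))
})

test_that("poly-T insert lengths follow the configured distribution", {
  reg <- fixture_regions("appendicularia")[[10]] # an O. dioica row
  cfg <- synthetic_config(seed = 1234)
  s <- synthesize_fasta(rep(list(reg), 500), cfg, polyt = TRUE)
  meta <- attr(s, "meta")
  expect_true(all(!is.na(meta$polyt_length)))
  expect_true(all(meta$polyt_length >= cfg$polyt_min))
  expect_true(all(meta$polyt_length <= cfg$polyt_max))
  # empirical mean within 15% of the configured 140 nt
  expect_lt(abs(mean(meta$polyt_length) - 140) / 140, 0.15)
  # detected max runs agree with the planted insert (boundary Ts may extend it)
  reps <- polyt_report(s, min_len = 10)
  expect_true(all(reps$present))
  expect_true(all(reps$max_run >= meta$polyt_length))
})

test_that("records without inserts contain no qualifying run", {
  regs <- fixture_regions("thaliacea")
  s <- synthesize_fasta(regs, synthetic_config(seed = 77), polyt = FALSE)
  reps <- polyt_report(s, min_len = 10)
  expect_false(any(reps$present))
})
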