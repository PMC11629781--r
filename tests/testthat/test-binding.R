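ml <- get_primer("mlCOIintF")
xt <- get_primer("mlCOIintF-XT")
jg <- get_primer("jgHCO2198")
hco <- get_primer("HCO2198")

test_that("locate_binding_site recovers planted sites exactly", {
  set.seed(11)
  exp_rows <- enumerate_expansions(ml$sequence)
  for (i in 1:5) {
    site <- paste(exp_rows[sample.int(nrow(exp_rows), 1), ], collapse = "")
    template <- paste0(random_concrete_seq(10), site, random_concrete_seq(30))
    reg <- locate_binding_site(template, ml)
    expect_identical(reg$start, 10L)
    expect_identical(attr(reg, "mismatches"), 0L)
    expect_identical(reg$covered, "full")
  }
  # a fixture region used as its own template
  r2 <- fixture_regions("oithona_similis")[[2]]
  loc <- locate_binding_site(r2$bases, ml)
  expect_identical(loc$start, 0L)
  expect_identical(loc$covered, "full")
})

test_that("locator score equals the exhaustive sliding-window minimum", {
  set.seed(23)
  for (i in 1:10) {
    template <- random_concrete_seq(500)
    # plant a site with exactly 3 mutations at a random offset
    reg <- random_region(ml, 3)
    at <- sample.int(500 - 26, 1)
    template <- paste0(substr(template, 1, at), reg$bases,
                       substr(template, at + 27, 500))
    got <- locate_binding_site(template, ml, max_scan_mismatches = 26L)
    want <- brute_force_locate(template, ml$sequence)
    expect_identical(attr(got, "mismatches"), as.integer(want[["score"]]))
    expect_identical(got$start, as.integer(want[["start"]]))
    expect_lte(attr(got, "mismatches"), 3L)
  }
})

test_that("locator edge cases: empty, short, and hopeless templates", {
  expect_error(locate_binding_site("", ml), "empty template")
  short <- locate_binding_site("ACGTACGT", ml)
  expect_identical(short$covered, "partial")
  set.seed(5)
  far <- locate_binding_site(random_concrete_seq(60), ml, max_scan_mismatches = 0L)
  expect_identical(far$covered, "none")
})

test_that("profiles against fixture lineages match the published mismatch structure", {
  regs <- fixture_regions("oithona_similis")
  names(regs) <- vapply(regs, function(r) r$source_id, character(1))

  p2 <- profile_mismatches(ml, regs[["#II"]])
  expect_identical(p2$total, 2L)
  expect_identical(p2$mismatch_positions, c(12L, 18L))
  expect_false(p2$terminal3_hit)
  expect_identical(profile_mismatches(xt, regs[["#II"]])$total, 0L)

  p7 <- profile_mismatches(xt, regs[["#VII"]])
  expect_identical(p7$total, 4L)
  expect_true(p7$terminal3_hit)

  # identity: any concrete expansion of the primer profiles clean
  set.seed(3)
  exp_rows <- enumerate_expansions(ml$sequence)
  site <- paste(exp_rows[sample.int(nrow(exp_rows), 1), ], collapse = "")
  expect_identical(profile_mismatches(ml, site)$total, 0L)

  expect_error(profile_mismatches(ml, "ACGT"), "length")
})

test_that("profile totals equal the brute-force expansion minimum Hamming distance", {
  set.seed(41)
  for (i in 1:20) {
    primer <- random_degenerate_primer(len = 12L)
    region <- random_concrete_seq(12L)
    got <- profile_mismatches(primer, region)$total
    want <- min_hamming_to_expansions(primer$sequence, region)
    expect_identical(got, as.integer(want),
                     info = sprintf("%s vs %s", primer$sequence, region))
  }
})

test_that("ambiguous template positions match anything but are flagged", {
  region <- paste0("N", substr(ml$sequence, 2, 26))
  region <- gsub("[RYSWKMBDHVNI]", "A", region) # concretise the rest crudely
  region <- paste0("N", substr(region, 2, 26))
  prof <- profile_mismatches(ml, region)
  expect_identical(prof$per_position[1], "ambiguous-template")
  expect_false(1L %in% prof$mismatch_positions)
})

test_that("risk classification applies the documented thresholds", {
  regs <- fixture_regions("oithona_similis")
  names(regs) <- vapply(regs, function(r) r$source_id, character(1))

  lvl <- function(prof) as.character(classify_risk(prof)$level)

  clean <- gsub("Y", "C", gsub("W", "A", ml$sequence))
  expect_identical(lvl(profile_mismatches(ml, clean)), "negligible")

  # lineage #XI: 6 mismatches incl. position 24 -> failure under mlCOIintF
  expect_identical(lvl(profile_mismatches(ml, regs[["#XI"]])), "failure_likely")
  # lineage #II: 2 internal mismatches -> reduced, 1/10 misdetection rationale
  r2 <- classify_risk(profile_mismatches(ml, regs[["#II"]]))
  expect_identical(as.character(r2$level), "reduced")
  expect_match(r2$rationale, "1/10")
  # one terminal mismatch alone is severe
  term1 <- random_region(ml, 1, terminal = TRUE, seed = 9)
  expect_identical(lvl(profile_mismatches(ml, term1)), "severe")
  # 3 mismatches with a terminal hit -> failure_likely
  t3 <- random_region(ml, 3, terminal = TRUE, seed = 10)
  expect_identical(lvl(profile_mismatches(ml, t3)), "failure_likely")
  # 4 internal mismatches without terminal hit -> failure_likely
  set.seed(12)
  repeat {
    r4 <- random_region(ml, 4)
    if (!profile_mismatches(ml, r4)$terminal3_hit) break
  }
  expect_identical(lvl(profile_mismatches(ml, r4)), "failure_likely")
})

test_that("risk is monotone: adding a mismatch never lowers the level", {
  set.seed(77)
  for (i in 1:30) {
    k <- sample(0:5, 1)
    reg <- random_region(ml, k, terminal = sample(c(TRUE, FALSE), 1) && k > 0)
    prof <- profile_mismatches(ml, reg)
    base_level <- classify_risk(prof)$level
    # flip one currently-matching, mismatch-capable position
    chars <- strsplit(reg$bases, "")[[1]]
    pchars <- strsplit(ml$sequence, "")[[1]]
    free <- setdiff(which(vapply(pchars, function(s)
      length(allowed_bases(s)) < 4, logical(1))), prof$mismatch_positions)
    if (length(free) == 0) next
    p <- free[sample.int(length(free), 1)]
    chars[p] <- setdiff(c("A", "C", "G", "T"), allowed_bases(pchars[p]))[1]
    worse <- classify_risk(profile_mismatches(ml, paste(chars, collapse = "")))$level
    expect_gte(as.integer(worse), as.integer(base_level))
  }
})

test_that("reverse primers are profiled against the binding strand", {
  set.seed(19)
  # planted exact expansion of jgHCO2198: no mismatches
  exp_rows <- enumerate_expansions(jg$sequence)
  binding <- paste(exp_rows[sample.int(nrow(exp_rows), 1), ], collapse = "")
  template <- paste0(random_concrete_seq(40), reverse_complement(binding),
                     random_concrete_seq(15))
  prof <- profile_reverse(jg, template)
  expect_identical(prof$total, 0L)

  # a single substitution on the binding strand maps to the primer coordinate
  # (inosine positions accept anything, so only non-universal positions can
  # host a forced mismatch)
  capable <- unname(which(vapply(strsplit(jg$sequence, "")[[1]],
                                 function(s) length(allowed_bases(s)) < 4, logical(1))))
  for (i in 1:10) {
    k <- capable[sample.int(length(capable), 1)]
    chars <- strsplit(binding, "")[[1]]
    pool <- setdiff(c("A", "C", "G", "T"), allowed_bases(substr(jg$sequence, k, k)))
    chars[k] <- pool[1]
    mut <- paste(chars, collapse = "")
    template <- paste0(random_concrete_seq(20), reverse_complement(mut),
                       random_concrete_seq(20))
    prof <- profile_reverse(jg, template)
    expect_identical(prof$mismatch_positions, k)
  }

  # jgHCO2198's ambiguity sets contain HCO2198's bases
  template <- paste0(random_concrete_seq(10), reverse_complement(hco$sequence),
                     random_concrete_seq(10))
  expect_identical(profile_reverse(jg, template)$total, 0L)

  # too-short template yields a partial, not an error
  partial <- profile_reverse(jg, "ACGTACGT")
  expect_true(is.na(partial$total))
  expect_identical(attr(partial, "region")$covered, "partial")
})
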