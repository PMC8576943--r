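test_that("each retention rule removes calls and logs its name", {
  ## rows: ok, low alt reads, homopolymer below / above 10%, high popAF
  vt <- makeTable(depth = cbind(s1 = c(100L, 10L, 100L, 100L, 100L)),
                  alt   = cbind(s1 = c(40L, 1L, 8L, 12L, 40L)),
                  homopolymer = c(FALSE, FALSE, TRUE, TRUE, FALSE),
                  population_af = c(0, 0, 0, 0, 0.05))
  vt <- applyFilters(vt)
  pres <- presence(vt)[, 1]
  expect_equal(unname(pres), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  log <- filterLog(vt)
  expect_equal(log$rule[log$variant_id == rownames(vt)[2]], "min_alt_reads")
  expect_equal(log$rule[log$variant_id == rownames(vt)[3]], "homopolymer")
  expect_equal(log$rule[log$variant_id == rownames(vt)[5]],
               "max_population_af")
})

test_that("depth rule accepts coverage in tumor or matched normal", {
  ## tumor depth 8 (< 10) but normal depth 100: retained; af = 3/8 = 0.375
  vt <- applyFilters(makeTable(depth = cbind(s1 = 8L), alt = cbind(s1 = 3L),
                               normal_depth = 100L))
  expect_true(presence(vt)[1, 1])
  vt2 <- applyFilters(makeTable(depth = cbind(s1 = 8L), alt = cbind(s1 = 3L),
                                normal_depth = 5L))
  expect_false(presence(vt2)[1, 1])
  expect_equal(filterLog(vt2)$rule, "min_depth")
})

test_that("an empty table filters to an empty table with an empty log", {
  vt <- makeTable(depth = matrix(integer(), 0, 2,
                                 dimnames = list(NULL, c("s1", "s2"))),
                  alt = matrix(integer(), 0, 2))
  vt <- applyFilters(vt)
  expect_equal(nrow(presence(vt)), 0L)
  expect_equal(nrow(filterLog(vt)), 0L)
})

test_that("cross-sample recovery rescues low-AF calls with an anchor", {
  ## v1: 12% / 3% -> both present after recovery (3% has 3 alt reads)
  ## v2: 3% / 4%  -> no anchor, absent everywhere
  vt <- makeTableAf(cbind(s1 = c(0.12, 0.03), s2 = c(0.03, 0.04)))
  vt <- applyFilters(vt)
  expect_equal(unname(presence(vt)[1, ]), c(TRUE, FALSE))
  rec <- recoverVariants(vt)
  expect_equal(unname(presence(rec)[1, ]), c(TRUE, TRUE))
  expect_equal(unname(presence(rec)[2, ]), c(FALSE, FALSE))
  ## rescued call leaves the removal log (conservation below checks the rest)
  expect_false(any(filterLog(rec)$variant_id == rownames(vt)[1] &
                     filterLog(rec)$sample == "s2"))
})

test_that("recovery is idempotent and never removes calls", {
  set.seed(7)
  for (i in 1:5) {
    af <- matrix(sample(c(0, 0.02, 0.03, 0.08, 0.3), 40, replace = TRUE),
                 10, 4)
    vt <- applyFilters(makeTableAf(af))
    r1 <- recoverVariants(vt)
    r2 <- recoverVariants(r1)
    expect_identical(presence(r1), presence(r2))
    expect_true(all(presence(r1) >= presence(vt)))
  }
})

test_that("filtering is monotone in the thresholds", {
  set.seed(8)
  af <- matrix(runif(60, 0, 0.3), 15, 4)
  vt <- makeTableAf(af)
  base <- presence(applyFilters(vt, filterRules()))
  for (rules in list(filterRules(min_af = 0.10),
                     filterRules(min_alt_reads = 10),
                     filterRules(min_depth = 150),
                     filterRules(max_population_af = 0))) {
    strict <- presence(applyFilters(vt, rules))
    expect_true(all(strict <= base))
  }
})

test_that("passing calls plus logged removals partition the input calls", {
  set.seed(9)
  vt <- applyFilters(makeTableAf(matrix(runif(30, 0, 0.2), 10, 3)))
  log <- filterLog(vt)
  pres <- presence(vt)
  n_pairs <- nrow(pres) * ncol(pres)
  expect_equal(sum(pres) + nrow(log), n_pairs)
  key_log <- paste(log$variant_id, log$sample)
  idx <- which(pres, arr.ind = TRUE)
  key_pass <- paste(rownames(pres)[idx[, 1]], colnames(pres)[idx[, 2]])
  expect_length(intersect(key_log, key_pass), 0)
})

test_that("TMB scales counts by panel size and is additive", {
  af <- cbind(s1 = rep(0.4, 10), s2 = c(rep(0.4, 4), rep(0, 6)))
  eff <- c(rep("missense", 6), rep("synonymous", 4))
  vt <- filteredTable(depth = matrix(100L, 10, 2,
                                     dimnames = list(NULL, c("s1", "s2"))),
                      alt = round(af * 100), effect = eff)
  tm <- tmb(vt, 40)
  ## s1 carries all 6 non-synonymous: 6/40; recount independently
  pres <- presence(vt)
  expect_equal(unname(tm["s1"]), sum(pres[eff != "synonymous", "s1"]) / 40)
  expect_equal(unname(tm["s1"]), 0.15)
  ## additivity over disjoint variant subsets
  expect_equal(tmb(vt[1:5, ], 40) + tmb(vt[6:10, ], 40), tm)
  expect_error(tmb(vt, 0), "panel_size_mb")
})

test_that("MSI classes partition the score range at 10 and 30", {
  expect_equal(classifyMsi(c(5, 9.9)), c("MSS", "MSS"))
  expect_equal(classifyMsi(c(10, 20, 30)), rep("MSI-L", 3))
  expect_equal(classifyMsi(c(30.1, 35, 100)), rep("MSI-H", 3))
  expect_error(classifyMsi(101))
  expect_error(classifyMsi(-1))
  ## every score maps to exactly one class
  expect_false(anyNA(classifyMsi(seq(0, 100, by = 0.5))))
})

test_that("VCF round trip preserves read counts, order and metadata", {
  vt <- simulateTumor(simConfig(seed = 21))
  f <- tempfile(fileext = ".vcf")
  writeVcf(vt, f)
  back <- readVcf(f)
  expect_identical(colnames(back), colnames(vt))
  expect_identical(assay(back, "depth"), assay(vt, "depth"))
  expect_identical(assay(back, "alt"), assay(vt, "alt"))
  expect_lt(max(abs(assay(back, "af") - assay(vt, "af"))), 1e-9)
  expect_equal(purity(back), purity(vt))
  expect_equal(tissueType(back), tissueType(vt))
  expect_equal(patientID(back), patientID(vt))
  expect_equal(as.data.frame(rowData(back)), as.data.frame(rowData(vt)),
               tolerance = 1e-12)
})

test_that("a missing FORMAT AF field is recomputed from AD and DP", {
  lines <- c("##fileformat=VCFv4.2",
             "##patient=p1",
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="d">',
             '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="a">',
             '##SAMPLE=<ID=s1,Purity=0.9,Tissue=primary>',
             '##SAMPLE=<ID=N,Purity=.,Tissue=normal>',
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "N", sep = "\t"),
             paste("1", "100", "v1", "A", "T", ".", "PASS", ".",
                   "DP:AD", "80:60,20", "70:70,0", sep = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  vt <- readVcf(f)
  expect_equal(unname(assay(vt, "af")[1, "s1"]), 20 / 80)
  expect_equal(unname(purity(vt)["s1"]), 0.9)
  expect_error(readVcf(textConnectionPathHack <- {
    g <- tempfile(); writeLines("not a vcf", g); g
  }), "parse error")
})
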