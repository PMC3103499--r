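test_that("hypergeometric upper tail matches exact enumeration", {
  expect_identical(hypergeom_upper_pvalue(10, 4, 5, 0), 1.0)
  expect_identical(hypergeom_upper_pvalue(10, 10, 5, 3), 1.0)
  expect_equal(hypergeom_upper_pvalue(10, 4, 5, 3), 66 / 252,
               tolerance = 1e-14)
  # full small grid against the rational oracle, >= 12 significant digits
  for (B in c(5L, 12L, 25L)) {
    for (b in unique(c(0L, 1L, B %/% 3L, B))) {
      for (N in unique(c(1L, B %/% 2L, B))) {
        for (n in 0:min(N, b)) {
          want <- oracle_hyper(B, b, N, n)
          got <- hypergeom_upper_pvalue(B, b, N, n)
          expect_equal(got, want, tolerance = 1e-12)
        }
      }
    }
  }
  # and against R's own tail at a large background
  expect_equal(hypergeom_upper_pvalue(5000, 37, 8, 6),
               stats::phyper(5, 37, 5000 - 37, 8, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(hypergeom_upper_pvalue(10, 11, 5, 2), "bounds")
  expect_error(hypergeom_upper_pvalue(10, 4, 5, 5), "bounds")
})

test_that("p-value is monotone in n and in b", {
  set.seed(401)
  for (rep in 1:20) {
    B <- sample(50:500, 1)
    N <- sample(4:20, 1)
    b <- sample(N:(B - 1), 1)
    ns <- 0:min(N, b)
    p_by_n <- vapply(ns, function(n) hypergeom_upper_pvalue(B, b, N, n), 1)
    expect_true(all(diff(p_by_n) <= 1e-12))
    n <- sample(1:min(N, b), 1)
    bs <- seq(n, B, length.out = 5)
    p_by_b <- vapply(round(bs), function(bb)
      hypergeom_upper_pvalue(B, bb, N, n), 1)
    expect_true(all(diff(p_by_b) >= -1e-12))
  }
})

test_that("background hit counting uses raw presence and ignores order", {
  cfg <- scenario_config(seed = 41, background_size = 400, decoy_rate = 2,
                         leak_rate = 37 / 400,
                         modules = module_spec(c("+NFKB", "-CREB"),
                                               gap_range = c(5, 30)))
  bg <- generate_background(cfg)
  expect_length(bg$truth$carriers, 37L)
  b <- count_background_hits(c("+NFKB", "-CREB"), bg$genes)
  expect_gte(b, 37L) # carriers plus possible decoy coincidences
  # all truth carriers really carry it
  for (g in bg$truth$carriers[1:5]) {
    expect_true(gene_min_instance(bg$genes[[g]], c("+NFKB", "-CREB"))$present)
  }
  # order invariance
  expect_identical(count_background_hits(c("+NFKB", "-CREB"),
                                         rev(bg$genes)), b)
  # vocabulary absent from the background
  expect_identical(count_background_hits(c("+QQQQ"), bg$genes), 0L)
})

test_that("score_crm fills the hypergeometric p-value", {
  cfg <- scenario_config(seed = 42, background_size = 500, decoy_rate = 2,
                         leak_rate = 30 / 500,
                         modules = module_spec(c("+NFKB", "-CREB"),
                                               n_genes = 8, fraction = 0.75,
                                               gap_range = c(5, 30)))
  bat <- generate_battery(cfg)
  bg <- generate_background(cfg)
  crm <- evaluate_module(c("+NFKB", "-CREB"), bat$genes)
  scored <- score_crm(crm, bg$genes)
  b <- count_background_hits(c("+NFKB", "-CREB"), bg$genes)
  n <- length(crm$support_genes)
  expect_equal(scored$p_value, oracle_hyper(500, b, 8, n),
               tolerance = 1e-10)

  # n = 0 gives p = 1; support exceeding background hits gives p = 0
  empty <- evaluate_module(c("+QQQQ", "-CREB"), bat$genes)
  expect_identical(score_crm(empty, bg$genes)$p_value, 1.0)
  null_cfg <- scenario_config(seed = 43, background_size = 50,
                              decoy_rate = 0, leak_rate = 0)
  null_bg <- generate_background(null_cfg)
  expect_identical(score_crm(crm, null_bg$genes)$p_value, 0)
})

test_that("calibration is seed-reproducible with the documented floor", {
  cfg <- scenario_config(seed = 44, background_size = 60, decoy_rate = 6,
                         vocabulary = paste0("F", 1:6),
                         promoters_per_gene = c(1, 2), leak_rate = 0)
  bg <- generate_background(cfg)
  sc <- search_config(max_module_size = 2)
  t1 <- calibrate_thresholds(bg$genes, sizes = 4:6, reps = 4, config = sc,
                             seed = 99)
  t2 <- calibrate_thresholds(bg$genes, sizes = 4:6, reps = 4, config = sc,
                             seed = 99)
  expect_identical(t1, t2)
  t3 <- calibrate_thresholds(bg$genes, sizes = 4:6, reps = 4, config = sc,
                             seed = 100)
  expect_false(identical(t1$raw_mean, t3$raw_mean))

  # floor rule: N >= floor_size entries equal the floor threshold
  tf <- calibrate_thresholds(bg$genes, sizes = 13:15, reps = 2, config = sc,
                             seed = 7)
  expect_identical(tf$threshold[tf$N >= 14], c(0.01, 0.01))
  expect_error(calibrate_thresholds(bg$genes, sizes = c(4, 100), reps = 1,
                                    config = sc, seed = 1), "exceeds")
  expect_error(calibrate_thresholds(bg$genes, sizes = 4, reps = 1,
                                    config = sc), "seed")
})

test_that("a site-free background calibrates to threshold 1", {
  cfg <- scenario_config(seed = 45, background_size = 40, decoy_rate = 0,
                         leak_rate = 0)
  bg <- generate_background(cfg)
  tab <- calibrate_thresholds(bg$genes, sizes = 4:6, reps = 3,
                              config = search_config(max_module_size = 2),
                              seed = 5)
  expect_identical(tab$raw_mean, rep(1, 3))
  expect_identical(tab$threshold, rep(1, 3))
})

test_that("calibration tables round-trip through disk", {
  cfg <- scenario_config(seed = 46, background_size = 40, decoy_rate = 3,
                         leak_rate = 0)
  bg <- generate_background(cfg)
  tab <- calibrate_thresholds(bg$genes, sizes = 4:5, reps = 2,
                              config = search_config(max_module_size = 2),
                              seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_calibration(tab, f)
  back <- read_calibration(f)
  expect_equal(back$threshold, tab$threshold, tolerance = 0)
  expect_identical(attr(back, "seed"), attr(tab, "seed"))
  expect_identical(attr(back, "delta"), attr(tab, "delta"))
})

test_that("select_significant filters strictly below the threshold", {
  mk <- function(label, p) {
    crm <- evaluate_module(parse_crm_label(label),
                           span_battery(list(g1 = 100, g2 = 100)))
    crm$p_value <- p
    crm
  }
  crms <- structure(list(mk("+A__-B", 1e-5), mk("+B__-A", 1e-4),
                         mk("+A__-A", 2e-3)), class = c("crm_set", "list"))
  out <- select_significant(crms, N = 8, alpha = 1e-4)
  expect_identical(vapply(out, `[[`, "", "label"), "+A__-B") # 1e-4 excluded
  expect_length(select_significant(structure(list(),
                                             class = c("crm_set", "list")),
                                   N = 8, alpha = 0.05), 0L)
  tab <- structure(data.frame(N = 8L, threshold = 1e-3, raw_mean = 1e-3),
                   class = c("calibration_table", "data.frame"))
  out2 <- select_significant(crms, N = 8, thresholds = tab)
  expect_identical(vapply(out2, `[[`, "", "label"), c("+A__-B", "+B__-A"))
  expect_error(select_significant(crms, N = 12, thresholds = tab),
               "calibrate")
  expect_error(select_significant(crms, N = 8), "alpha")
})

test_that("a genome-wide shared module is insignificant against its own
           background but significant against an i.i.d. one", {
  voc <- paste0("F", 1:10)
  shared <- scenario_config(seed = 47, vocabulary = voc,
                            background_size = 300,
                            promoters_per_gene = c(1, 1), decoy_rate = 4,
                            modules = module_spec(c("+F1", "+F2"),
                                                  gap_range = c(5, 40)),
                            leak_rate = 1.0)
  iid <- scenario_config(seed = 48, vocabulary = voc, background_size = 300,
                         promoters_per_gene = c(1, 1), decoy_rate = 6,
                         leak_rate = 0)
  bg_shared <- generate_background(shared)
  bg_iid <- generate_background(iid)
  # a battery drawn from the shared background carries the module
  set.seed(49)
  draw <- sample(names(bg_shared$genes), 6)
  crm <- evaluate_module(c("+F1", "+F2"), bg_shared$genes[draw])
  expect_true(crm$common)
  p_shared <- score_crm(crm, bg_shared$genes)$p_value
  p_iid <- score_crm(crm, bg_iid$genes)$p_value
  expect_gt(p_shared, 0.5)  # b ~ B: sharing explains the commonness
  expect_lt(p_iid, 1e-4)    # same support is a strong signal vs i.i.d.
})

test_that("null batteries rarely beat the calibrated threshold", {
  voc <- paste0("F", 1:8)
  cfg <- scenario_config(seed = 50, vocabulary = voc, background_size = 250,
                         promoters_per_gene = c(1, 1), decoy_rate = 8,
                         leak_rate = 0)
  bg <- generate_background(cfg)
  sc <- search_config(max_module_size = 2)
  tab <- calibrate_thresholds(bg$genes, sizes = 4, reps = 15, config = sc,
                              seed = 51)
  thr <- tab$threshold[1]
  packed <- pack_profiles(bg$genes)
  reps <- 30L
  below <- 0L
  for (r in seq_len(reps)) {
    set.seed(5000 + r)
    draw <- sample(names(bg$genes), 4)
    crms <- search_common_crms(bg$genes[draw], sc)
    pmin_r <- if (!length(crms)) 1 else {
      min(vapply(score_crms(crms, packed), `[[`, 1, "p_value"))
    }
    if (pmin_r < thr) below <- below + 1L
  }
  # threshold is a mean of minima: fresh null draws beat it at a
  # bounded rate (sanity bound, not a sharp type-I statement)
  expect_lte(below / reps, 0.75)
})
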