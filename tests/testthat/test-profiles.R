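test_that("promoter profiles sort, deduplicate and index sites", {
  # worked hash-table example: forward ETSF at -386 and -373 upstream
  p <- build_promoter_profile("g1", "g1.p1",
    binding_sites("ETSF", c(-373, -386), c(-361, -374), "+"))
  expect_identical(p$index, list("+ETSF" = c(-386L, -373L)))
  expect_identical(p$sites$start, c(-386L, -373L))

  # duplicates collapse; sites sorted by (start, end)
  dup <- data.frame(factor_id = c("A", "A", "B"), start = c(-50, -50, -200),
                    end = c(-40, -40, -190), orientation = c("+", "+", "-"))
  p2 <- build_promoter_profile("g", "p", dup)
  expect_identical(nrow(p2$sites), 2L)
  expect_identical(p2$sites$factor_id, c("B", "A"))

  # empty promoter
  p0 <- build_promoter_profile("g", "p0", NULL)
  expect_length(p0$index, 0L)
  expect_false(has_oriented_site(p0, "+ETSF"))

  # malformed record names the promoter
  bad <- data.frame(factor_id = "A", start = -10, end = -20,
                    orientation = "+")
  expect_error(build_promoter_profile("g", "pX", bad), "pX")
})

test_that("profile construction is order-invariant and rebuildable", {
  set.seed(101)
  sites <- data.frame(
    factor_id = sample(LETTERS[1:5], 20, replace = TRUE),
    start = sample(-500:50, 20), orientation = sample(c("+", "-"), 20,
                                                      replace = TRUE))
  sites$end <- sites$start + sample(5:20, 20, replace = TRUE)
  p1 <- build_promoter_profile("g", "p", sites[sample(20), ])
  p2 <- build_promoter_profile("g", "p", sites[sample(20), ])
  expect_identical(p1, p2)
  # rebuilding the index from the sites reproduces it bit-identically
  p3 <- build_promoter_profile("g", "p", p1$sites)
  expect_identical(p3$index, p1$index)
})

test_that("has_oriented_site respects orientation and validates keys", {
  p <- build_promoter_profile("g1", "g1.p1",
    binding_sites("ETSF", c(-386, -373), c(-374, -361), "+"))
  expect_true(has_oriented_site(p, "+ETSF"))
  expect_false(has_oriented_site(p, "-ETSF"))
  expect_false(has_oriented_site(p, "−ETSF")) # typographic minus ok
  expect_error(has_oriented_site(p, "ETSF"), "malformed")
})

test_that("find_min_instance matches hand-built cases", {
  # singleton: ties broken toward the most-upstream first site
  p <- build_promoter_profile("g", "p",
    binding_sites("A", c(-400, -50), c(-389, -39), "+"))
  i1 <- find_min_instance(p, "+A")
  expect_identical(i1$span, 12L)
  expect_identical(i1$first_start, -400L)

  # ordered pair +A@-300..-290, -B@-200..-190 -> span 111; reversed
  # element order has no instance
  pr <- build_promoter_profile("g", "p", data.frame(
    factor_id = c("A", "B"), start = c(-300, -200), end = c(-290, -190),
    orientation = c("+", "-")))
  expect_identical(find_min_instance(pr, c("+A", "-B"))$span, 111L)
  expect_null(find_min_instance(pr, c("-B", "+A")))
  expect_error(find_min_instance(pr, character()), "non-empty")
})

test_that("find_min_instance agrees with the brute-force oracle", {
  set.seed(202)
  vocab <- LETTERS[1:4]
  keys <- as.vector(outer(c("+", "-"), vocab, paste0))
  for (rep in 1:40) {
    p <- random_profile("g", "p", vocab, sample(0:25, 1))
    m <- sample(1:4, 1)
    elems <- sample(keys, m, replace = TRUE)
    got <- find_min_instance(p, elems)
    want <- oracle_min_span(p, elems)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$span, as.integer(want))
      # returned refs must themselves be a valid ordered instance
      s <- p$sites[got$site_refs, ]
      expect_identical(s$key, elems)
      if (nrow(s) > 1) expect_true(all(diff(s$start) > 0) &&
                                     all(s$start[-1] > s$end[-nrow(s)]))
    }
  }
})

test_that("packed kernel agrees with the R matcher", {
  set.seed(203)
  vocab <- LETTERS[1:5]
  keys <- as.vector(outer(c("+", "-"), vocab, paste0))
  genes <- lapply(1:12, function(i) {
    random_gene(sprintf("g%02d", i), vocab, sample(1:3, 1))
  })
  packed <- pack_profiles(genes)
  for (rep in 1:25) {
    elems <- sample(keys, sample(1:4, 1), replace = TRUE)
    spans_cpp <- crmbattery:::packed_min_spans(packed, elems)
    tab <- battery_presence_vector(genes, elems)
    expect_identical(unname(is.na(spans_cpp)), !tab$present)
    expect_equal(unname(spans_cpp[tab$present]),
                 as.numeric(tab$span[tab$present]))
  }
})

test_that("gene_min_instance applies the alternative-promoter heuristic", {
  sites2 <- data.frame(factor_id = c("A", "B"), start = c(-300, -200),
                       end = c(-290, -190), orientation = c("+", "-"))
  g <- gene_profile("g", list(
    build_promoter_profile("g", "g.p1", NULL),
    build_promoter_profile("g", "g.p2", sites2),
    build_promoter_profile("g", "g.p3",
                           binding_sites("C", -100, -90, "+"))))
  hit <- gene_min_instance(g, c("+A", "-B"))
  expect_true(hit$present)
  expect_identical(hit$instance$promoter_id, "g.p2")
  expect_identical(hit$span, 111L)

  miss <- gene_min_instance(g, c("+Z"))
  expect_false(miss$present)
  expect_true(is.na(miss$span))

  # minimum span across promoters: 140 on p1 vs 95 on p2 -> 95
  mk <- function(pid, span) {
    data.frame(factor_id = c("A", "B"), start = c(-400, -400 + span - 10),
               end = c(-391, -400 + span - 1), orientation = c("+", "-"))
  }
  g2 <- gene_profile("h", list(
    build_promoter_profile("h", "h.p1", mk("h.p1", 140)),
    build_promoter_profile("h", "h.p2", mk("h.p2", 95))))
  expect_identical(gene_min_instance(g2, c("+A", "-B"))$span, 95L)
})

test_that("battery_presence_vector is consistent and validates input", {
  set.seed(204)
  genes <- lapply(1:8, function(i) random_gene(sprintf("g%d", i),
                                               LETTERS[1:3], 2))
  elems <- c("+A", "-B")
  tab <- battery_presence_vector(genes, elems)
  expect_identical(nrow(tab), 8L)
  for (i in c(1, 4, 8)) {
    one <- gene_min_instance(genes[[i]], elems)
    expect_identical(tab$present[i], one$present)
    expect_identical(tab$span[i], one$span)
  }
  expect_identical(nrow(battery_presence_vector(list(), elems)), 0L)
  expect_error(battery_presence_vector(c(genes, genes[1]), elems),
               "duplicate")
})

test_that("site tables round-trip through disk", {
  set.seed(205)
  genes <- lapply(1:5, function(i) random_gene(sprintf("g%d", i),
                                               c("NFKB", "CREB", "SP1F"),
                                               sample(1:3, 1)))
  genes <- genes[vapply(genes, function(g) {
    sum(vapply(g$promoters, function(p) nrow(p$sites), 1L)) > 0
  }, TRUE)]
  tab <- as_site_table(genes)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(tab, f)
  back <- read_site_table(f)
  expect_identical(build_gene_profiles(back),
                   build_gene_profiles(tab))
})

test_that("prefix and suffix sub-modules of a present module are present", {
  set.seed(206)
  vocab <- LETTERS[1:4]
  keys <- as.vector(outer(c("+", "-"), vocab, paste0))
  hits <- 0L
  for (rep in 1:60) {
    g <- random_gene("g", vocab, sample(1:2, 1), max_sites = 15L)
    elems <- sample(keys, 3, replace = TRUE)
    if (!gene_min_instance(g, elems)$present) next
    hits <- hits + 1L
    for (k in 1:2) {
      expect_true(gene_min_instance(g, elems[1:k])$present)      # prefix
      expect_true(gene_min_instance(g, elems[(k + 1):3])$present) # suffix
    }
  }
  expect_gt(hits, 3L) # the property was actually exercised
})

test_that("GFF3 genome coordinates convert to TSS-relative sites", {
  gff <- c("##gff-version 3",
           paste("chr1", "src", "TFBS", "1100", "1111", ".", "+", ".",
                 "factor_id=NFKB;gene_id=g1;promoter_id=g1.p1",
                 sep = "\t"),
           paste("chr1", "src", "TFBS", "2080", "2091", ".", "+", ".",
                 "factor_id=CREB;gene_id=g2;promoter_id=g2.p1",
                 sep = "\t"))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, f)
  tss <- data.frame(promoter_id = c("g1.p1", "g2.p1"),
                    tss = c(1500L, 2000L), gene_strand = c("+", "-"))
  tab <- read_site_table_gff3(f, tss)
  # plus-strand gene: 1100..1111 with TSS 1500 -> -400..-389, same strand
  expect_identical(tab$start[1], -400L)
  expect_identical(tab$end[1], -389L)
  expect_identical(tab$orientation[1], "+")
  # minus-strand gene: 2080..2091 with TSS 2000 -> axis flipped,
  # orientation re-expressed relative to the gene
  expect_identical(tab$start[2], -91L)
  expect_identical(tab$end[2], -80L)
  expect_identical(tab$orientation[2], "-")
})
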