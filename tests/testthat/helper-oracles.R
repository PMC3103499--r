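# Independent oracles and small generators. Everything here is kept
# deliberately naive (enumeration, no pruning, no greedy shortcuts) so
# it cannot share a defect with the implementation it checks.

# All ordered, non-overlapping, key-matching site selections on one
# promoter, by exhaustive enumeration; returns minimal span or NULL.
oracle_min_span <- function(profile, elements) {
  sites <- profile$sites
  cand <- lapply(elements, function(e) which(sites$key == e))
  if (any(lengths(cand) == 0L)) return(NULL)
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    if (anyDuplicated(idx)) next
    ok <- TRUE
    if (length(idx) > 1L) {
      for (k in 2:length(idx)) {
        if (sites$start[idx[k]] <= sites$end[idx[k - 1L]]) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    span <- sites$end[idx[length(idx)]] - sites$start[idx[1L]] + 1L
    if (is.null(best) || span < best) best <- span
  }
  best
}

# Gene-level oracle: minimum over all promoters.
oracle_gene_min_span <- function(gene, elements) {
  spans <- unlist(lapply(gene$promoters, oracle_min_span,
                         elements = elements))
  if (is.null(spans) || !length(spans)) NULL else min(spans)
}

# Exact hypergeometric upper tail by direct term enumeration with
# base-R choose() (exact in double precision for B <= ~25).
oracle_hyper <- function(B, b, N, n) {
  if (n == 0) return(1.0)
  i <- seq(n, min(N, b))
  sum(choose(b, i) * choose(B - b, N - i)) / choose(B, N)
}

# Random promoter profile over a key vocabulary (independent of the
# package's synthetic generators).
random_profile <- function(gene_id, promoter_id, vocab, n_sites,
                           region = c(-500L, 100L), width_range = c(5L, 20L)) {
  if (n_sites == 0L) {
    return(build_promoter_profile(gene_id, promoter_id, NULL))
  }
  w <- sample(width_range[1]:width_range[2], n_sites, replace = TRUE)
  s <- sample(region[1]:(region[2] - max(w)), n_sites, replace = TRUE)
  build_promoter_profile(gene_id, promoter_id, data.frame(
    factor_id = sample(vocab, n_sites, replace = TRUE),
    start = s, end = s + w - 1L,
    orientation = sample(c("+", "-"), n_sites, replace = TRUE),
    stringsAsFactors = FALSE))
}

random_gene <- function(gene_id, vocab, k_promoters, max_sites = 12L) {
  gene_profile(gene_id, lapply(seq_len(k_promoters), function(k) {
    random_profile(gene_id, paste0(gene_id, ".p", k), vocab,
                   sample(0:max_sites, 1L))
  }))
}

# Unpruned brute-force common-CRM search: enumerate every ordered tuple
# over the FULL oriented vocabulary and keep those evaluate_module
# flags common. Exponential; only for tiny instances.
brute_force_common_crms <- function(genes, config, vocab_keys) {
  labels <- character()
  for (m in config$min_module_size:config$max_module_size) {
    grid <- do.call(expand.grid,
                    c(rep(list(vocab_keys), m),
                      list(KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)))
    for (r in seq_len(nrow(grid))) {
      elems <- as.character(unlist(grid[r, ]))
      crm <- evaluate_module(elems, genes, config)
      if (crm$common) labels <- c(labels, crm$label)
    }
  }
  sort(labels, method = "radix")
}

# Union over all per-gene promoter combinations of the common-CRM sets
# found when each gene is reduced to a single fixed promoter.
combo_union_common_crms <- function(genes, config) {
  kk <- lapply(genes, function(g) seq_along(g$promoters))
  combos <- do.call(expand.grid, c(kk, list(KEEP.OUT.ATTRS = FALSE)))
  labels <- character()
  for (r in seq_len(nrow(combos))) {
    fixed <- lapply(seq_along(genes), function(i) {
      g <- genes[[i]]
      gene_profile(g$gene_id, g$promoters[as.integer(combos[r, i])])
    })
    crms <- search_common_crms(fixed, config)
    labels <- c(labels, vapply(crms, `[[`, "", "label"))
  }
  sort(unique(labels), method = "radix")
}

# Element sequences that are ordered subsequences of a planted label.
is_subsequence_of <- function(label, planted_label) {
  x <- parse_crm_label(label)
  y <- parse_crm_label(planted_label)
  j <- 1L
  for (i in seq_along(y)) {
    if (j <= length(x) && identical(x[j], y[i])) j <- j + 1L
  }
  j == length(x) + 1L
}

# Deterministic single-instance battery: each gene carries exactly the
# given span for the module (one promoter, no other sites), absent
# genes get an empty promoter. Used for arithmetic-oracle tests of the
# length band.
span_battery <- function(spans_by_gene, elements = c("+A", "-B")) {
  lapply(names(spans_by_gene), function(g) {
    span <- spans_by_gene[[g]]
    if (is.na(span)) {
      return(gene_profile(g, list(build_promoter_profile(g, paste0(g, ".p1"),
                                                         NULL))))
    }
    spl <- data.frame(factor_id = substring(elements, 2),
                      orientation = substring(elements, 1, 1))
    w <- 10L
    m <- length(elements)
    stopifnot(span >= m * w)
    # first m-1 sites packed tightly, last site placed to hit the span
    starts <- c(-400L + (seq_len(m - 1L) - 1L) * w,
                -400L + span - w)
    sites <- data.frame(factor_id = spl$factor_id, start = starts,
                        end = starts + w - 1L,
                        orientation = spl$orientation,
                        stringsAsFactors = FALSE)
    gene_profile(g, list(build_promoter_profile(g, paste0(g, ".p1"), sites)))
  })
}
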