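# Common CRM search: breadth-first combination of common oriented
# TFBSs into ordered, oriented, non-overlapping modules, with the
# round-up support rule and the half-to-double instance-length band.

#' Search configuration
#'
#' @param delta support fraction threshold: a module is common when at
#'   least `ceiling(delta * N)` of the N battery genes carry a
#'   length-consistent instance (default 0.7).
#' @param min_module_size,max_module_size module sizes (number of
#'   oriented sites) explored, defaults 2 and 4.
#' @param length_band multipliers of the average instance span between
#'   which an instance counts toward support, default `c(0.5, 2)` (the
#'   half-to-double rule). Use `c(0, Inf)` to disable the band.
#' @return a `search_config` list.
#' @export
search_config <- function(delta = 0.7, min_module_size = 2L,
                          max_module_size = 4L, length_band = c(0.5, 2)) {
  stopifnot(delta > 0, delta <= 1,
            min_module_size >= 1, min_module_size <= max_module_size,
            length(length_band) == 2, length_band[1] >= 0,
            length_band[1] < 1, length_band[2] > 1)
  structure(list(delta = delta,
                 min_module_size = as.integer(min_module_size),
                 max_module_size = as.integer(max_module_size),
                 length_band = as.numeric(length_band)),
            class = "search_config")
}

#' Round-up support rule
#'
#' The minimum number of supporting genes required for a module to be
#' common in a battery of N genes at support fraction `delta`:
#' `ceiling(delta * N)`, evaluated with decimal semantics (a small
#' guard keeps binary floating point from pushing an exact product such
#' as 0.7 x 10 = 7 over the next integer). Consecutive battery sizes
#' can share the same requirement, e.g. sizes 6 and 7 both need 5 genes
#' at delta = 0.7.
#'
#' @param N battery size (genes), `N >= 1`.
#' @param delta support fraction in (0, 1].
#' @return integer number of genes.
#' @examples
#' required_support(8, 0.7) # 6
#' required_support(6, 0.7) # 5
#' required_support(7, 0.7) # 5
#' @export
required_support <- function(N, delta = 0.7) {
  if (any(N < 1) || any(N != round(N))) {
    stop("N must be a positive integer", call. = FALSE)
  }
  stopifnot(delta > 0, delta <= 1)
  as.integer(ceiling(delta * N - 1e-9))
}

#' Common oriented TFBSs of a battery
#'
#' Oriented keys present (gene-level presence under the
#' alternative-promoter heuristic) in at least `required_support(N,
#' delta)` of the N battery genes; these are the seeds of the module
#' search.
#'
#' @param genes list of [gene_profile()] objects or a
#'   [pack_profiles()] result.
#' @param config a [search_config()].
#' @return character vector of oriented keys in canonical (radix sort)
#'   order.
#' @export
common_oriented_tfbs <- function(genes, config = search_config()) {
  packed <- pack_profiles(genes)
  N <- length(packed$gene_ids)
  stopifnot(N >= 1)
  req <- required_support(N, config$delta)
  pres <- packed_key_presence(packed)
  sort_c(colnames(pres)[colSums(pres) >= req])
}

#' Canonical CRM label
#'
#' Elements joined by `"__"` with orientation prefixes, e.g.
#' `"+NFKB__-CREB__-SP1F"`. [parse_crm_label()] is its inverse; factor
#' names therefore must not contain `"__"`.
#'
#' @param elements module elements (oriented keys or a
#'   factor_id/orientation data.frame).
#' @return single label string.
#' @examples
#' crm_label(c("+AP4R", "-GATA", "-HEAT"))
#' parse_crm_label("+E2FF__+MOKF__-E2FF")
#' @export
crm_label <- function(elements) {
  elements <- as_elements(elements)
  if (any(grepl("__", elements, fixed = TRUE))) {
    stop("factor_id must not contain '__'", call. = FALSE)
  }
  paste(elements, collapse = "__")
}

#' @rdname crm_label
#' @param label a label string (U+2212 minus accepted).
#' @return for `parse_crm_label`, a character vector of oriented keys.
#' @export
parse_crm_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  parts <- strsplit(label, "__", fixed = TRUE)[[1L]]
  if (!length(parts) || any(!nzchar(parts))) {
    stop("malformed CRM label: '", label, "'", call. = FALSE)
  }
  as_elements(parts)
}

# Core evaluation given precomputed per-gene minimal spans.
evaluate_spans <- function(elements, spans, config) {
  N <- length(spans)
  req <- required_support(N, config$delta)
  raw <- names(spans)[!is.na(spans)]
  inst <- spans[!is.na(spans)]
  if (length(inst)) {
    avg <- mean(inst)
    lo <- config$length_band[1] * avg
    hi <- config$length_band[2] * avg
    supp <- names(inst)[inst >= lo & inst <= hi]
    lens <- c(avg = avg, min = min(inst), max = max(inst))
  } else {
    supp <- character()
    lens <- c(avg = NA_real_, min = NA_real_, max = NA_real_)
  }
  structure(list(
    elements = elements,
    label = crm_label(elements),
    size = length(elements),
    n_battery = N,
    raw_support = sort_c(raw),
    support_genes = sort_c(supp),
    avg_len = unname(lens["avg"]),
    min_len = unname(lens["min"]),
    max_len = unname(lens["max"]),
    common_level = length(supp) / N,
    common = length(supp) >= req,
    p_value = NA_real_
  ), class = "crm")
}

#' Evaluate one candidate module against a battery
#'
#' Collects the per-gene minimal instance spans (alternative-promoter
#' heuristic), averages them over all genes with any instance, applies
#' the instance-length band around that average, and flags the module
#' common when the band-filtered support reaches
#' `required_support(N, delta)`. The average is computed once, before
#' the band filter (no re-averaging).
#'
#' @param elements ordered module elements (oriented keys).
#' @inheritParams common_oriented_tfbs
#' @return object of class `crm` with fields elements, label, size,
#'   n_battery, raw_support / support_genes (gene id vectors), avg_len,
#'   min_len, max_len (bp over per-gene minimal instances),
#'   common_level, common, p_value (NA until scored).
#' @export
evaluate_module <- function(elements, genes, config = search_config()) {
  elements <- as_elements(elements)
  packed <- pack_profiles(genes)
  evaluate_spans(elements, packed_min_spans(packed, elements), config)
}

#' @export
print.crm <- function(x, ...) {
  cat("<crm> ", x$label, "  support ", length(x$support_genes), "/",
      x$n_battery, " (raw ", length(x$raw_support), "), common_level ",
      signif(x$common_level, 3), if (x$common) ", common" else "",
      if (!is.na(x$p_value)) paste0(", p = ", signif(x$p_value, 3)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Search all common CRMs of a gene battery
#'
#' Breadth-first search over ordered tuples (repeats of a factor
#' allowed) of the battery's common oriented TFBSs, module sizes
#' `min_module_size..max_module_size`. A tuple is extended only while
#' its raw gene-level presence support (before the length band) reaches
#' `required_support(N, delta)` — raw presence is anti-monotone under
#' extension, the band-filtered count is not. Every explored tuple is
#' kept in the result when its band-filtered support makes it common.
#'
#' @inheritParams common_oriented_tfbs
#' @return object of class `crm_set`: list of common [crm][evaluate_module]
#'   objects ordered by (size, label).
#' @export
search_common_crms <- function(genes, config = search_config()) {
  packed <- pack_profiles(genes)
  N <- length(packed$gene_ids)
  stopifnot(N >= 1)
  req <- required_support(N, config$delta)
  keys <- common_oriented_tfbs(packed, config)
  found <- list()
  frontier <- lapply(keys, function(k) k)
  size <- 1L
  while (length(frontier) && size < config$max_module_size) {
    size <- size + 1L
    nxt <- list()
    for (base in frontier) {
      for (k in keys) {
        elems <- c(base, k)
        spans <- packed_min_spans(packed, elems)
        raw_n <- sum(!is.na(spans))
        if (raw_n < req) next
        nxt[[length(nxt) + 1L]] <- elems
        if (size >= config$min_module_size) {
          crm <- evaluate_spans(elems, spans, config)
          if (crm$common) found[[crm$label]] <- crm
        }
      }
    }
    frontier <- nxt
  }
  if (config$min_module_size <= 1L) {
    for (k in keys) {
      crm <- evaluate_spans(k, packed_min_spans(packed, k), config)
      if (crm$common) found[[crm$label]] <- crm
    }
  }
  found <- unname(found)
  if (length(found)) {
    o <- order(vapply(found, `[[`, 1L, "size"),
               vapply(found, `[[`, "", "label"), method = "radix")
    found <- found[o]
  }
  structure(found, class = c("crm_set", "list"))
}

#' @export
print.crm_set <- function(x, ...) {
  cat("<crm_set> ", length(x), " common CRM(s)\n", sep = "")
  for (crm in head(x, 10L)) print(crm)
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Tabulate a CRM set
#'
#' @param x a `crm_set` (or list of `crm` objects).
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns label, size, avg_len, min_len,
#'   max_len, common_level, support_genes (comma-separated ids),
#'   raw_support (count), p_value.
#' @export
as.data.frame.crm_set <- function(x, row.names = NULL, optional = FALSE,
                                  ...) {
  data.frame(
    label = vapply(x, `[[`, "", "label"),
    size = vapply(x, `[[`, 1L, "size"),
    avg_len = vapply(x, `[[`, 1, "avg_len"),
    min_len = vapply(x, `[[`, 1, "min_len"),
    max_len = vapply(x, `[[`, 1, "max_len"),
    common_level = vapply(x, `[[`, 1, "common_level"),
    support_genes = vapply(x, function(c) paste(c$support_genes,
                                                collapse = ","), ""),
    raw_support = vapply(x, function(c) length(c$raw_support), 1L),
    p_value = vapply(x, `[[`, 1, "p_value"),
    stringsAsFactors = FALSE
  )
}

#' Write a CRM report TSV
#'
#' @param crms a `crm_set`.
#' @param path output file.
#' @export
write_crm_report <- function(crms, path) {
  data.table::fwrite(as.data.frame.crm_set(crms), path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}
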