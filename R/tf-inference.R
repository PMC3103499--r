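# TF inference: decompose significant CRMs into TF families, apply the
# cross-battery frequency rule, and export the regulatory edge list.

#' Decompose CRMs into transcription factors
#'
#' Union of the element factor names of a battery's significant CRMs,
#' orientation stripped (a factor binding forward in one module and
#' backward in another is one factor), deduplicated and sorted.
#'
#' @param crms a `crm_set` (already significance-filtered) or a
#'   character vector of CRM labels.
#' @return sorted character vector of factor ids.
#' @examples
#' decompose_crms(c("+AP4R__-GATA__-HEAT", "+E2FF__+MOKF__-E2FF"))
#' @export
decompose_crms <- function(crms) {
  if (is.character(crms)) {
    keys <- unlist(lapply(crms, parse_crm_label), use.names = FALSE)
  } else {
    keys <- unlist(lapply(crms, `[[`, "elements"), use.names = FALSE)
  }
  if (!length(keys)) return(character())
  sort_c(unique(split_oriented_key(keys)$factor_id))
}

#' Critical transcription factors across batteries
#'
#' Factors whose TFBSs occur in the significant CRMs of at least
#' `min_batteries` gene batteries (each battery counts once however
#' many of its CRMs contain the factor).
#'
#' @param factor_sets named list: battery_id -> factor ids (typically
#'   [decompose_crms()] per battery).
#' @param min_batteries frequency threshold (default 3).
#' @return data.frame with columns factor_id, count, batteries
#'   (comma-separated battery ids), sorted by descending count then
#'   factor name.
#' @export
critical_tfs <- function(factor_sets, min_batteries = 3L) {
  stopifnot(length(factor_sets) >= 1L)
  if (is.null(names(factor_sets)) || any(!nzchar(names(factor_sets)))) {
    stop("factor_sets must be named by battery_id", call. = FALSE)
  }
  long <- data.frame(
    factor_id = unlist(lapply(factor_sets, unique), use.names = FALSE),
    battery_id = rep(names(factor_sets),
                     vapply(factor_sets, function(x) length(unique(x)), 1L)),
    stringsAsFactors = FALSE)
  if (!nrow(long)) {
    return(data.frame(factor_id = character(), count = integer(),
                      batteries = character(), stringsAsFactors = FALSE))
  }
  sets <- split(long$battery_id, long$factor_id)
  out <- data.frame(
    factor_id = names(sets),
    count = lengths(sets),
    batteries = vapply(sets, function(b) paste(sort_c(b), collapse = ","),
                       ""),
    stringsAsFactors = FALSE)
  out <- out[out$count >= min_batteries, , drop = FALSE]
  out <- out[order(-out$count, out$factor_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Regulatory edge list
#'
#' One edge per (factor appearing in a battery's significant CRMs) x
#' (gene of that battery), annotated with the battery's pattern and
#' pathway — the flat-file form of a TF-target network.
#'
#' @param batteries list of batteries (see [build_batteries()]).
#' @param significant_crms named list: battery_id -> significant
#'   `crm_set` (or character labels).
#' @return data.frame with columns factor_id, gene_id, pattern,
#'   pathway, battery_id in deterministic order.
#' @export
regulatory_edges <- function(batteries, significant_crms) {
  names(batteries) <- vapply(batteries, `[[`, "", "battery_id")
  rows <- lapply(sort_c(names(significant_crms)), function(bid) {
    bat <- batteries[[bid]]
    if (is.null(bat)) {
      stop("significant CRMs for unknown battery '", bid, "'",
           call. = FALSE)
    }
    factors <- decompose_crms(significant_crms[[bid]])
    if (!length(factors)) return(NULL)
    genes <- sort_c(bat$genes)
    data.frame(factor_id = rep(factors, each = length(genes)),
               gene_id = rep(genes, times = length(factors)),
               pattern = bat$pattern, pathway = bat$pathway,
               battery_id = bid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(factor_id = character(), gene_id = character(),
                      pattern = character(), pathway = character(),
                      battery_id = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write TF report / edge list TSVs
#'
#' `write_edges_graph` additionally emits a minimal tab-separated
#' `source target` file loadable by common network viewers.
#'
#' @param x a [critical_tfs()] or [regulatory_edges()] data.frame.
#' @param path output file.
#' @export
write_tf_report <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_tf_report
#' @export
write_edges <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_tf_report
#' @export
write_edges_graph <- function(x, path) {
  writeLines(c("source\ttarget",
               sprintf("%s\t%s", x$factor_id, x$gene_id)), path)
  invisible(path)
}
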