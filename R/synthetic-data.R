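# Seeded synthetic promoter worlds with planted CRMs: backgrounds,
# batteries, and expression/pathway fixtures with truth records, so
# every stage of the method is testable without external data.

# The 34 TF family names the in vivo analysis reports as critical
# regulators; used as the default site vocabulary.
default_tf_vocabulary <- function() {
  c("AP4R", "ATBF", "BRNF", "CLOX", "CREB", "E2FF", "EBOX", "EGRF",
    "EKLF", "ETSF", "FKHD", "GATA", "HEAT", "HOMF", "HOXF", "IRFF",
    "MAZF", "MEF2", "MOKF", "MYBL", "MYT1", "MZF1", "NFKB", "NKXH",
    "NR2F", "OCT1", "PARF", "PAX6", "RXRF", "SORY", "SP1F", "STAT",
    "TBPF", "ZBPF")
}

#' Planted-module specification
#'
#' Describes one module to plant: its ordered oriented elements, the
#' battery size, the fraction of battery genes that carry an instance,
#' and the inter-site gap distribution which controls span dispersion
#' (and therefore whether the half-to-double band bites).
#'
#' @param elements ordered oriented keys (default the top module of the
#'   reference battery, `+AP4R__-GATA__-HEAT`).
#' @param n_genes battery size N (default 8).
#' @param fraction planted fraction of carriers in `[0, 1]` (default
#'   0.75; carriers number `ceiling(fraction * n_genes)`).
#' @param gap_range inclusive integer range for i.i.d. uniform
#'   inter-site gaps in bp (default 20..50, which keeps every planted
#'   instance inside the half-to-double band by construction; gaps >= 1
#'   keep sites non-overlapping).
#' @param gap_sampler optional `function(carrier_index, n_gaps)`
#'   returning the gap vector for one carrier, overriding `gap_range`
#'   (used to force span outliers).
#' @param site_width planted site width in bp (default 12).
#' @param width_jitter max +/- jitter added to each planted site width
#'   (default 0).
#' @return a `module_spec` list.
#' @export
module_spec <- function(elements = c("+AP4R", "-GATA", "-HEAT"),
                        n_genes = 8L, fraction = 0.75,
                        gap_range = c(20L, 50L), gap_sampler = NULL,
                        site_width = 12L, width_jitter = 0L) {
  elements <- as_elements(elements)
  stopifnot(fraction >= 0, fraction <= 1, n_genes >= 1,
            gap_range[1] >= 1, gap_range[2] >= gap_range[1],
            site_width >= 1, width_jitter >= 0)
  structure(list(elements = elements, label = crm_label(elements),
                 n_genes = as.integer(n_genes), fraction = fraction,
                 gap_range = as.integer(gap_range),
                 gap_sampler = gap_sampler,
                 site_width = as.integer(site_width),
                 width_jitter = as.integer(width_jitter)),
            class = "module_spec")
}

#' Synthetic-scenario configuration
#'
#' The stated world the generators emulate: a background of B genes
#' with one to a few alternative promoters each, i.i.d. decoy sites
#' over a TF-family vocabulary placed uniformly on the default promoter
#' region (-500..+100), planted modules in batteries, and a small
#' background leak of planted instances.
#'
#' @param seed mandatory master seed; every generator draw derives from
#'   it.
#' @param vocabulary TF family names used for decoy sites (default: the
#'   34 inflammation-relevant families).
#' @param background_size B, number of background genes (default 5000).
#' @param promoters_per_gene inclusive integer range for the number of
#'   alternative promoters K_i per gene (default 1..4).
#' @param decoy_rate expected (Poisson) decoy site count per promoter
#'   (default 8).
#' @param region promoter extent relative to the TSS, default
#'   `c(-500, 100)`.
#' @param site_width decoy site width in bp (default 12).
#' @param modules list of [module_spec()]s to plant (default one).
#' @param leak_rate fraction of background genes that also receive one
#'   instance of the first planted module (default 0.01).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(seed,
                            vocabulary = default_tf_vocabulary(),
                            background_size = 5000L,
                            promoters_per_gene = c(1L, 4L),
                            decoy_rate = 8,
                            region = c(-500L, 100L),
                            site_width = 12L,
                            modules = list(module_spec()),
                            leak_rate = 0.01) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(vocabulary) >= 1, background_size >= 1,
            promoters_per_gene[1] >= 1,
            promoters_per_gene[2] >= promoters_per_gene[1],
            decoy_rate >= 0, region[1] < region[2],
            leak_rate >= 0, leak_rate <= 1)
  if (inherits(modules, "module_spec")) modules <- list(modules)
  structure(list(seed = as.integer(seed),
                 vocabulary = as.character(vocabulary),
                 background_size = as.integer(background_size),
                 promoters_per_gene = as.integer(promoters_per_gene),
                 decoy_rate = decoy_rate,
                 region = as.integer(region),
                 site_width = as.integer(site_width),
                 modules = modules,
                 leak_rate = leak_rate),
            class = "scenario_config")
}

# Draw one planted instance of a module; returns a site-table chunk.
# Gaps come from the module's sampler (default i.i.d. uniform over
# gap_range); the first start is uniform over placements that fit the
# region. Resamples gaps when the instance cannot fit.
plant_instance <- function(config, module, gene_id, promoter_id,
                           carrier_index) {
  m <- length(module$elements)
  spl <- split_oriented_key(module$elements)
  for (try in 1:100) {
    widths <- module$site_width + (if (module$width_jitter > 0)
      sample(seq(-module$width_jitter, module$width_jitter), m,
             replace = TRUE) else rep(0L, m))
    widths <- pmax(widths, 1L)
    gaps <- if (!is.null(module$gap_sampler)) {
      as.integer(module$gap_sampler(carrier_index, m - 1L))
    } else if (m > 1L) {
      sample(seq(module$gap_range[1], module$gap_range[2]), m - 1L,
             replace = TRUE)
    } else integer()
    if (m > 1L && any(gaps < 1L)) {
      stop("inter-site gaps must be >= 1", call. = FALSE)
    }
    span <- sum(widths) + sum(gaps)
    lo <- config$region[1]
    hi <- config$region[2] - span + 1L
    if (hi < lo) next # does not fit; resample gaps
    first <- if (hi > lo) sample(seq(lo, hi), 1L) else lo
    starts <- first + cumsum(c(0L, head(widths, -1L) + gaps))
    return(data.frame(gene_id = gene_id, promoter_id = promoter_id,
                      factor_id = spl$factor_id, start = as.integer(starts),
                      end = as.integer(starts + widths - 1L),
                      orientation = spl$orientation,
                      stringsAsFactors = FALSE))
  }
  stop("planted instance of '", module$label, "' cannot fit the region ",
       config$region[1], "..", config$region[2], call. = FALSE)
}

# Decoy sites for one promoter; exact duplicates of planted sites on
# the same promoter are redrawn so truth records stay unambiguous.
decoy_sites <- function(config, gene_id, promoter_id, planted = NULL) {
  n <- rpois(1L, config$decoy_rate)
  if (n == 0L) return(NULL)
  draw <- function(k) {
    start <- sample(seq(config$region[1],
                        config$region[2] - config$site_width + 1L),
                    k, replace = TRUE)
    data.frame(gene_id = gene_id, promoter_id = promoter_id,
               factor_id = sample(config$vocabulary, k, replace = TRUE),
               start = as.integer(start),
               end = as.integer(start + config$site_width - 1L),
               orientation = sample(c("+", "-"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  out <- draw(n)
  if (!is.null(planted)) {
    for (try in 1:50) {
      clash <- paste(out$factor_id, out$start, out$end, out$orientation) %in%
        paste(planted$factor_id, planted$start, planted$end,
              planted$orientation)
      if (!any(clash)) break
      out[clash, ] <- draw(sum(clash))
    }
  }
  out
}

# Promoter ids for a gene: "<gene>.p1", "<gene>.p2", ...
promoter_ids <- function(gene_id, k) paste0(gene_id, ".p", seq_len(k))

#' Generate a synthetic background gene set
#'
#' B genes, each with K_i alternative promoters carrying i.i.d. decoy
#' sites; a `leak_rate` fraction of genes (rounded) additionally carry
#' one planted instance of the first configured module on one randomly
#' chosen promoter. Identical seeds give identical site tables.
#'
#' @param config a [scenario_config()].
#' @param prefix gene-id prefix (default `"bg"`).
#' @return list with `genes` (a gene_profile_set), `site_table`, and
#'   `truth` (planted labels, carrier gene ids, per-carrier instance
#'   coordinates).
#' @export
generate_background <- function(config, prefix = "bg") {
  set.seed(derive_seed(config$seed, 1L))
  B <- config$background_size
  ids <- sprintf("%s%05d", prefix, seq_len(B))
  kk <- sample(seq(config$promoters_per_gene[1],
                   config$promoters_per_gene[2]), B, replace = TRUE)
  n_leak <- round(config$leak_rate * B)
  leak <- if (n_leak > 0) sort_c(sample(ids, n_leak)) else character()
  module <- config$modules[[1L]]
  chunks <- vector("list", B)
  planted_rows <- list()
  for (i in seq_len(B)) {
    pids <- promoter_ids(ids[i], kk[i])
    planted <- NULL
    if (ids[i] %in% leak) {
      planted <- plant_instance(config, module, ids[i],
                                sample(pids, 1L), i)
      planted_rows[[ids[i]]] <- planted
    }
    dec <- lapply(pids, function(pid) {
      decoy_sites(config, ids[i], pid,
                  if (!is.null(planted) && planted$promoter_id[1] == pid)
                    planted else NULL)
    })
    # promoters with neither decoys nor planted sites still exist but
    # carry no rows; presence queries on them are trivially false.
    chunks[[i]] <- do.call(rbind, c(dec[!vapply(dec, is.null, TRUE)],
                                    list(planted)))
  }
  site_table <- do.call(rbind, chunks[!vapply(chunks, is.null, TRUE)])
  if (is.null(site_table)) {
    site_table <- data.frame(gene_id = character(), promoter_id = character(),
                             factor_id = character(), start = integer(),
                             end = integer(), orientation = character(),
                             stringsAsFactors = FALSE)
  }
  rownames(site_table) <- NULL
  genes <- profiles_with_empty_promoters(site_table, ids, kk)
  truth <- structure(list(module_labels = module$label, carriers = leak,
                          instances = planted_rows),
                     class = "truth_record")
  list(genes = genes, site_table = site_table, truth = truth)
}

# Build profiles from a site table but keep promoters that received no
# sites (every gene keeps its K_i promoters).
profiles_with_empty_promoters <- function(site_table, ids, kk) {
  base <- if (nrow(site_table)) build_gene_profiles(site_table) else list()
  genes <- list()
  for (i in seq_along(ids)) {
    gid <- ids[i]
    pids <- promoter_ids(gid, kk[i])
    have <- if (!is.null(base[[gid]])) base[[gid]]$promoters else list()
    proms <- lapply(pids, function(pid) {
      have[[pid]] %||% build_promoter_profile(gid, pid, NULL)
    })
    genes[[gid]] <- gene_profile(gid, proms)
  }
  structure(genes, class = c("gene_profile_set", "list"))
}

#' Generate a synthetic gene battery with a planted module
#'
#' `ceiling(fraction * N)` carrier genes receive one instance of the
#' module on one randomly chosen alternative promoter (exercising the
#' alternative-promoter heuristic); all promoters of all genes receive
#' decoy sites at the configured rate.
#'
#' @param config a [scenario_config()].
#' @param module a [module_spec()] (default `config$modules[[1]]`).
#' @param prefix gene-id prefix (default `"bat"`).
#' @return list with `genes`, `site_table`, and `truth` (carriers and
#'   per-carrier instance coordinates and spans).
#' @export
generate_battery <- function(config, module = config$modules[[1L]],
                             prefix = "bat") {
  set.seed(derive_seed(config$seed, 2L, module$n_genes))
  N <- module$n_genes
  ids <- sprintf("%s%03d", prefix, seq_len(N))
  kk <- sample(seq(config$promoters_per_gene[1],
                   config$promoters_per_gene[2]), N, replace = TRUE)
  n_car <- as.integer(ceiling(module$fraction * N))
  carriers <- if (n_car > 0) sort_c(sample(ids, n_car)) else character()
  chunks <- list(); planted_rows <- list()
  for (i in seq_len(N)) {
    pids <- promoter_ids(ids[i], kk[i])
    planted <- NULL
    if (ids[i] %in% carriers) {
      ci <- match(ids[i], carriers)
      planted <- plant_instance(config, module, ids[i], sample(pids, 1L), ci)
      planted_rows[[ids[i]]] <- planted
    }
    dec <- lapply(pids, function(pid) {
      decoy_sites(config, ids[i], pid,
                  if (!is.null(planted) && planted$promoter_id[1] == pid)
                    planted else NULL)
    })
    chunks[[i]] <- do.call(rbind, c(dec[!vapply(dec, is.null, TRUE)],
                                    list(planted)))
  }
  site_table <- do.call(rbind, chunks[!vapply(chunks, is.null, TRUE)])
  if (is.null(site_table)) {
    site_table <- data.frame(gene_id = character(), promoter_id = character(),
                             factor_id = character(), start = integer(),
                             end = integer(), orientation = character(),
                             stringsAsFactors = FALSE)
  }
  rownames(site_table) <- NULL
  genes <- profiles_with_empty_promoters(site_table, ids, kk)
  spans <- vapply(planted_rows, function(p) {
    max(p$end) - min(p$start) + 1L
  }, 1L)
  truth <- structure(list(module_labels = module$label, carriers = carriers,
                          instances = planted_rows, spans = spans),
                     class = "truth_record")
  list(genes = genes, site_table = site_table, truth = truth)
}

#' Generate an expression-pattern / pathway fixture
#'
#' Emits pattern assignments, a GMT pathway collection and a gene
#' universe engineered so that [build_batteries()] recovers exactly the
#' configured (pattern, pathway, size) layout at the given alpha:
#' designated pairs receive their overlap genes plus neutral filler
#' drawn from genes outside every pattern (filler is shrunk until the
#' enrichment clears alpha); all other pairs have zero overlap and are
#' never significant.
#'
#' @param config a [scenario_config()] (only the seed is used).
#' @param layout data.frame with columns pattern, pathway, size; the
#'   default mirrors a 14-battery pattern-by-pathway layout over four
#'   temporal patterns.
#' @param pattern_sizes named integer vector of pattern sizes; defaults
#'   to 141/88/185/799 for early-up/middle-up/late-up/down.
#' @param universe_size total universe (default 2400; genes beyond the
#'   patterns belong to no pattern).
#' @param pathway_filler target number of non-pattern filler genes per
#'   pathway (default 10; reduced per pair when needed to clear alpha).
#' @param alpha enrichment level the fixture must meet (default 0.05).
#' @return list with `patterns`, `pathways`, `universe`, and `truth`
#'   (the realized layout data.frame).
#' @export
generate_expression_fixture <- function(config,
                                        layout = default_battery_layout(),
                                        pattern_sizes = c("early-up" = 141L,
                                                          "middle-up" = 88L,
                                                          "late-up" = 185L,
                                                          "down" = 799L),
                                        universe_size = 2400L,
                                        pathway_filler = 10L,
                                        alpha = 0.05) {
  set.seed(derive_seed(config$seed, 3L))
  layout <- layout[layout$size > 0, , drop = FALSE]
  stopifnot(sum(pattern_sizes) <= universe_size)
  universe <- sprintf("u%05d", seq_len(universe_size))
  patterns <- list()
  off <- 0L
  for (pat in names(pattern_sizes)) {
    patterns[[pat]] <- universe[(off + 1L):(off + pattern_sizes[pat])]
    off <- off + pattern_sizes[pat]
  }
  flat <- universe[(off + 1L):universe_size] # genes in no pattern
  used_flat <- 0L
  avail <- patterns # genes of each pattern not yet claimed by a battery
  pathways <- stats::setNames(vector("list", length(unique(layout$pathway))),
                              unique(layout$pathway))
  realized <- layout; realized$p_value <- NA_real_
  B <- universe_size
  # phase 1: draw each designated pair's overlap genes (disjoint within
  # a pattern, so batteries do not share genes)
  for (i in seq_len(nrow(layout))) {
    pat <- layout$pattern[i]
    n <- layout$size[i]
    if (length(avail[[pat]]) < n) {
      stop("pattern '", pat, "' too small for its batteries", call. = FALSE)
    }
    overlap <- sample(avail[[pat]], n)
    avail[[pat]] <- setdiff(avail[[pat]], overlap)
    pathways[[layout$pathway[i]]] <-
      c(pathways[[layout$pathway[i]]], overlap)
  }
  # phase 2: per pathway, add neutral filler but shrink it until every
  # designated pair still clears alpha against the pathway's FULL
  # membership (a pathway shared across patterns accumulates all their
  # overlaps into its background count b)
  for (pw in names(pathways)) {
    rows <- which(layout$pathway == pw)
    b0 <- length(pathways[[pw]])
    filler_n <- pathway_filler
    repeat {
      ps <- vapply(rows, function(i) {
        hypergeom_upper_pvalue(B, b0 + filler_n,
                               pattern_sizes[[layout$pattern[i]]],
                               layout$size[i])
      }, 1)
      if (all(ps < alpha) || filler_n == 0L) break
      filler_n <- filler_n - 1L
    }
    if (any(ps >= alpha)) {
      bad <- rows[which(ps >= alpha)[1L]]
      stop("fixture pair ", layout$pattern[bad], " x ", pw,
           " cannot clear alpha = ", alpha, call. = FALSE)
    }
    if (filler_n > 0) {
      if (used_flat + filler_n > length(flat)) {
        stop("not enough non-pattern genes for pathway filler",
             call. = FALSE)
      }
      pathways[[pw]] <- c(pathways[[pw]],
                          flat[(used_flat + 1L):(used_flat + filler_n)])
      used_flat <- used_flat + filler_n
    }
    realized$p_value[rows] <- ps
  }
  pathways <- lapply(pathways, function(x) sort_c(unique(x)))
  list(patterns = patterns, pathways = pathways, universe = universe,
       truth = realized)
}

#' Default 14-battery layout
#'
#' Four temporal patterns crossed with inflammation-relevant pathways,
#' with the gene counts of the reference in vivo analysis.
#'
#' @return data.frame with columns pattern, pathway, size.
#' @export
default_battery_layout <- function() {
  data.frame(
    pattern = c(rep("early-up", 3), rep("middle-up", 2), rep("late-up", 4),
                rep("down", 5)),
    pathway = c("Apoptosis", "Cytokine-cytokine receptor interaction",
                "Toll-like receptor signaling pathway",
                "Apoptosis", "Toll-like receptor signaling pathway",
                "Apoptosis", "Cytokine-cytokine receptor interaction",
                "Toll-like receptor signaling pathway",
                "Jak-STAT signaling pathway",
                "Citrate cycle (TCA cycle)", "Pyrimidine metabolism",
                "Pyruvate metabolism", "Ribosome",
                "Oxidative phosphorylation"),
    size = c(4L, 9L, 6L, 8L, 4L, 7L, 10L, 6L, 6L, 6L, 10L, 6L, 20L, 40L),
    stringsAsFactors = FALSE)
}

#' @rdname default_battery_layout
#' @export
small_battery_layout <- function() {
  data.frame(
    pattern = c("early-up", "early-up", "down"),
    pathway = c("Apoptosis", "Toll-like receptor signaling pathway",
                "Ribosome"),
    size = c(6L, 8L, 10L),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic scenario
#'
#' Composes [generate_expression_fixture()], per-battery module
#' planting and a background into one coherent world for end-to-end
#' runs: every designated battery gets its own planted module (random
#' elements over the vocabulary) carried by `fraction` of its genes;
#' all universe genes receive alternative promoters and decoy sites;
#' the background is generated independently at the configured size.
#'
#' @param config a [scenario_config()].
#' @param layout battery layout (see [generate_expression_fixture()]).
#' @param module_size number of elements per planted module (default 3).
#' @param fraction planted carrier fraction per battery (default 0.75).
#' @param ... passed to [generate_expression_fixture()].
#' @return list with `site_table` (universe genes), `background`
#'   (list: genes, site_table, truth), `patterns`, `pathways`,
#'   `universe`, `batteries_truth`, and `planted` (data.frame
#'   battery_id, label).
#' @export
generate_scenario <- function(config, layout = default_battery_layout(),
                              module_size = 3L, fraction = 0.75, ...) {
  fx <- generate_expression_fixture(config, layout = layout, ...)
  set.seed(derive_seed(config$seed, 4L))
  # promoters and decoys for every universe gene
  ids <- fx$universe
  kk <- sample(seq(config$promoters_per_gene[1],
                   config$promoters_per_gene[2]),
               length(ids), replace = TRUE)
  names(kk) <- ids
  planted <- data.frame(battery_id = character(), label = character(),
                        stringsAsFactors = FALSE)
  planted_by_gene <- list()
  for (i in seq_len(nrow(fx$truth))) {
    pat <- fx$truth$pattern[i]; pw <- fx$truth$pathway[i]
    bid <- paste(pat, pw, sep = "|")
    genes <- intersect(fx$patterns[[pat]], fx$pathways[[pw]])
    spl <- data.frame(
      factor_id = sample(config$vocabulary, module_size, replace = FALSE),
      orientation = sample(c("+", "-"), module_size, replace = TRUE),
      stringsAsFactors = FALSE)
    mod <- module_spec(oriented_key(spl$factor_id, spl$orientation),
                       n_genes = length(genes), fraction = fraction)
    n_car <- as.integer(ceiling(fraction * length(genes)))
    carriers <- if (n_car > 0) sample(genes, n_car) else character()
    for (g in carriers) {
      inst <- plant_instance(config, mod, g,
                             sample(promoter_ids(g, kk[[g]]), 1L),
                             match(g, carriers))
      planted_by_gene[[g]] <- rbind(planted_by_gene[[g]], inst)
    }
    planted <- rbind(planted, data.frame(battery_id = bid, label = mod$label,
                                         stringsAsFactors = FALSE))
  }
  chunks <- list()
  for (g in ids) {
    pl <- planted_by_gene[[g]]
    dec <- lapply(promoter_ids(g, kk[[g]]), function(pid) {
      decoy_sites(config, g, pid,
                  if (!is.null(pl)) pl[pl$promoter_id == pid, , drop = FALSE]
                  else NULL)
    })
    chunks[[g]] <- do.call(rbind, c(dec[!vapply(dec, is.null, TRUE)],
                                    list(pl)))
  }
  site_table <- do.call(rbind, chunks[!vapply(chunks, is.null, TRUE)])
  if (is.null(site_table)) {
    site_table <- data.frame(gene_id = character(), promoter_id = character(),
                             factor_id = character(), start = integer(),
                             end = integer(), orientation = character(),
                             stringsAsFactors = FALSE)
  }
  rownames(site_table) <- NULL
  bg <- generate_background(config)
  list(site_table = site_table, background = bg,
       patterns = fx$patterns, pathways = fx$pathways,
       universe = fx$universe, batteries_truth = fx$truth,
       planted = planted)
}

#' Write / read a scenario configuration file
#'
#' Flat `key: value` (DCF) file covering the scalar scenario fields and
#' the vocabulary; planted-module layouts stay programmatic.
#'
#' @param config a [scenario_config()].
#' @param path file path.
#' @export
write_scenario_config <- function(config, path) {
  m <- cbind(seed = config$seed,
             vocabulary = paste(config$vocabulary, collapse = ","),
             background_size = config$background_size,
             promoters_per_gene = paste(config$promoters_per_gene,
                                        collapse = ","),
             decoy_rate = config$decoy_rate,
             region = paste(config$region, collapse = ","),
             site_width = config$site_width,
             leak_rate = config$leak_rate)
  write.dcf(m, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  m <- read.dcf(path)
  r <- function(k) strsplit(m[1, k], ",", fixed = TRUE)[[1L]]
  scenario_config(seed = as.integer(m[1, "seed"]),
                  vocabulary = r("vocabulary"),
                  background_size = as.integer(m[1, "background_size"]),
                  promoters_per_gene = as.integer(r("promoters_per_gene")),
                  decoy_rate = as.numeric(m[1, "decoy_rate"]),
                  region = as.integer(r("region")),
                  site_width = as.integer(m[1, "site_width"]),
                  leak_rate = as.numeric(m[1, "leak_rate"]))
}
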