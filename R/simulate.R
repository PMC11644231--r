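#' Simulation configuration for synthetic two-condition RNA-seq counts
#'
#' Bundles and validates the parameters of the negative-binomial count
#' simulator. The defaults emulate a two-condition bulk RNA-seq experiment
#' with two biological replicates per condition, a moderate fraction of
#' differentially expressed (DE) genes with a planted two-fold effect, and
#' gene-wise overdispersion typical of well-behaved cell-line data.
#'
#' @param n_genes number of genes to simulate.
#' @param n_reps_per_group biological replicates per condition (>= 2).
#' @param de_fraction fraction of genes carrying a planted effect, in \[0,1).
#' @param effect_log2 absolute planted log2 fold change; the sign of each
#'   planted gene is drawn at random.
#' @param dispersion shared NB dispersion alpha, so that the count variance is
#'   `mu + alpha * mu^2`.
#' @param mean_log_range range (natural log scale) of the log-uniform baseline
#'   mean expression.
#' @param seed integer seed; every draw of the generator is governed by it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_reps_per_group = 2,
                       de_fraction = 0.1,
                       effect_log2 = 2,
                       dispersion = 0.1,
                       mean_log_range = c(log(20), log(5000)),
                       seed = 1) {
  check_positive_scalar(n_genes, "n_genes")
  if (n_reps_per_group < 2) stop_input("'n_reps_per_group' must be >= 2")
  if (!is.numeric(de_fraction) || de_fraction < 0 || de_fraction >= 1) {
    stop_input("'de_fraction' must lie in [0,1)")
  }
  if (de_fraction > 0 && de_fraction * n_genes < 1) {
    stop_input("'de_fraction' * 'n_genes' must be >= 1 when positive")
  }
  if (effect_log2 < 0) stop_input("'effect_log2' must be >= 0")
  check_positive_scalar(dispersion, "dispersion")
  if (length(mean_log_range) != 2L || diff(mean_log_range) < 0) {
    stop_input("'mean_log_range' must be an increasing pair")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_reps_per_group = as.integer(n_reps_per_group),
    de_fraction = de_fraction,
    effect_log2 = effect_log2,
    dispersion = dispersion,
    mean_log_range = mean_log_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a two-condition NB count matrix with planted DE genes
#'
#' Counts for gene g in sample j are drawn from a negative binomial with mean
#' `s_j * mu_gj` and shared dispersion alpha (variance `mu + alpha * mu^2`).
#' Per-sample size factors `s_j` are drawn log-uniform in \[0.5, 2\] so that
#' normalization has real work to do. Baseline means are log-uniform over
#' `mean_log_range`; a `de_fraction` subset of genes has its second-condition
#' mean multiplied by `2^(+-effect_log2)` with random sign.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `counts` (integer matrix, genes x samples,
#'   dimnames set), `samples` (data.frame with columns `sample`, `group`;
#'   groups are `ctrl` and `trt`), and `truth` (list with `de_genes`, a
#'   data.frame of planted genes and signed effects, plus the drawn
#'   `size_factors` and baseline means).
#' @export
simulate_counts <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  set.seed(cfg$seed)
  n <- cfg$n_reps_per_group
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  samples <- c(sprintf("ctrl_%d", seq_len(n)), sprintf("trt_%d", seq_len(n)))
  groups <- rep(c("ctrl", "trt"), each = n)

  mu0 <- exp(stats::runif(cfg$n_genes, cfg$mean_log_range[1], cfg$mean_log_range[2]))
  n_de <- floor(cfg$de_fraction * cfg$n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(cfg$n_genes, n_de)) else integer(0)
  signs <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
  effect <- rep(0, cfg$n_genes)
  effect[de_idx] <- signs * cfg$effect_log2

  mu <- cbind(matrix(mu0, cfg$n_genes, n),
              matrix(mu0 * 2^effect, cfg$n_genes, n))
  sf <- exp(stats::runif(2 * n, log(0.5), log(2)))
  mu_scaled <- sweep(mu, 2, sf, "*")
  counts <- matrix(stats::rnbinom(length(mu_scaled), mu = mu_scaled, size = 1 / cfg$dispersion),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, samples))

  list(
    counts = counts,
    samples = data.frame(sample = samples, group = groups, stringsAsFactors = FALSE),
    truth = list(
      de_genes = data.frame(gene = genes[de_idx],
                            effect_log2 = effect[de_idx],
                            stringsAsFactors = FALSE),
      size_factors = stats::setNames(sf, samples),
      baseline_mean = stats::setNames(mu0, genes)
    )
  )
}

#' Simulate a channel-scored interactome with planted network structure
#'
#' Builds a STRING-style edge list over the supplied genes with four planted
#' ingredients, each recorded in the returned truth:
#' \itemize{
#'   \item a hub cluster wired as a star plus leaf-leaf chords, with a tail
#'     path hanging off the hub so that the cluster's component has the
#'     largest diameter; the designated hub has maximal degree and
#'     betweenness;
#'   \item a ribosomal-protein clique attached to the hub component through a
#'     single leaf, mimicking the dense translation-machinery cluster that
#'     obscures hub analysis in real DEG networks;
#'   \item decoy edges supported only by the text-mining channel (all other
#'     channels zero), which must not survive evidence-channel filtering;
#'   \item sparse random background edges whose experimental scores span the
#'     high-confidence threshold.
#' }
#' Structural (hub, tail, ribosomal) edges carry high experimental and
#' database scores so they pass a 0.900 combined-score cut.
#'
#' @param genes character vector of all gene symbols in the universe.
#' @param de_genes genes to draw planted clusters from (these should be the
#'   differentially expressed genes so the planted structure survives the
#'   DEG restriction of the network stage).
#' @param hub_size number of nodes in the hub star (center + leaves).
#' @param tail_len length of the path attached to the hub.
#' @param n_chords number of leaf-leaf chord edges in the hub cluster.
#' @param ribo_size size of the ribosomal clique.
#' @param n_decoy number of text-mining-only decoy edges between DE genes.
#' @param n_background number of random background edges over the universe.
#' @param seed integer seed.
#'
#' @return list with `edges` (data.frame of class `channel_edges`: columns
#'   `gene_a`, `gene_b`, the seven channel scores in \[0,1\], and
#'   `combined_score`) and `truth` (list with `hub_gene`, `hub_cluster`,
#'   `ribosomal_genes`, `decoy_edges` data.frame).
#' @export
simulate_interactome <- function(genes, de_genes,
                                 hub_size = 10, tail_len = 3, n_chords = 2,
                                 ribo_size = 8, n_decoy = 20,
                                 n_background = 300, seed = 1) {
  de_genes <- unique(as.character(de_genes))
  if (!all(de_genes %in% genes)) stop_input("'de_genes' must be a subset of 'genes'")
  need <- hub_size + tail_len + ribo_size
  if (hub_size < 3 || ribo_size < 3) stop_input("hub and ribosomal clusters need >= 3 genes")
  if (need > length(de_genes)) {
    stop_input("not enough DE genes for the requested cluster sizes")
  }
  set.seed(seed)

  picked <- sample(de_genes, need)
  star <- picked[seq_len(hub_size)]
  tail_nodes <- picked[hub_size + seq_len(tail_len)]
  ribo <- picked[hub_size + tail_len + seq_len(ribo_size)]
  hub <- star[1L]
  leaves <- star[-1L]

  ea <- character(0); eb <- character(0); kind <- character(0)
  add <- function(a, b, k) {
    ea <<- c(ea, a); eb <<- c(eb, b); kind <<- c(kind, rep(k, length(a)))
  }
  # star + chords + tail
  add(rep(hub, length(leaves)), leaves, "hub")
  if (n_chords > 0) {
    ch <- matrix(sample(leaves, 2 * n_chords), ncol = 2)
    add(ch[, 1], ch[, 2], "hub")
  }
  if (tail_len > 0) add(c(hub, tail_nodes[-tail_len]), tail_nodes, "hub")
  # ribosomal clique, attached to the component via one leaf
  rc <- utils::combn(ribo, 2)
  add(rc[1, ], rc[2, ], "ribo")
  add(leaves[length(leaves)], ribo[1L], "ribo_link")

  # decoy edges: text-mining only, between DE genes, avoiding planted pairs
  planted_key <- {
    cp <- canonical_pair(ea, eb)
    paste(cp$a, cp$b)
  }
  n_try <- 0L
  dec_a <- character(0); dec_b <- character(0)
  while (length(dec_a) < n_decoy && n_try < 50L * n_decoy) {
    n_try <- n_try + 1L
    pr <- sample(de_genes, 2)
    cp <- canonical_pair(pr[1], pr[2])
    key <- paste(cp$a, cp$b)
    if (!key %in% planted_key && !key %in% paste(dec_a, dec_b)) {
      dec_a <- c(dec_a, cp$a); dec_b <- c(dec_b, cp$b)
    }
  }
  add(dec_a, dec_b, "decoy")

  # sparse background over the whole universe
  bg_a <- character(0); bg_b <- character(0)
  if (n_background > 0) {
    ia <- sample.int(length(genes), 3 * n_background, replace = TRUE)
    ib <- sample.int(length(genes), 3 * n_background, replace = TRUE)
    keep <- ia != ib
    cp <- canonical_pair(genes[ia[keep]], genes[ib[keep]])
    key <- paste(cp$a, cp$b)
    seen <- c(planted_key, paste(dec_a, dec_b))
    ok <- !duplicated(key) & !key %in% seen
    take <- which(ok)[seq_len(min(n_background, sum(ok)))]
    bg_a <- cp$a[take]; bg_b <- cp$b[take]
    add(bg_a, bg_b, "background")
  }

  m <- length(ea)
  z <- function() numeric(m)
  ed <- data.frame(gene_a = ea, gene_b = eb,
                   neighborhood = z(), fusion = z(), cooccurrence = z(),
                   coexpression = z(), experimental = z(), database = z(),
                   textmining = z(), stringsAsFactors = FALSE)
  is_struct <- kind %in% c("hub", "ribo", "ribo_link")
  ns <- sum(is_struct)
  ed$experimental[is_struct] <- stats::runif(ns, 0.92, 0.99)
  ed$database[is_struct] <- stats::runif(ns, 0.80, 0.95)
  ed$coexpression[is_struct] <- stats::runif(ns, 0.30, 0.80)
  is_dec <- kind == "decoy"
  ed$textmining[is_dec] <- stats::runif(sum(is_dec), 0.95, 0.999)
  is_bg <- kind == "background"
  nb <- sum(is_bg)
  ed$experimental[is_bg] <- stats::runif(nb, 0.30, 0.97)
  ed$textmining[is_bg] <- stats::runif(nb, 0, 0.5)
  ed$neighborhood[is_bg] <- stats::runif(nb, 0, 0.2)

  cp <- canonical_pair(ed$gene_a, ed$gene_b)
  ed$gene_a <- cp$a; ed$gene_b <- cp$b
  ed$combined_score <- recombine_score(ed, allowed_channels = STRING_CHANNELS)
  ed <- ed[order(ed$gene_a, ed$gene_b), , drop = FALSE]
  rownames(ed) <- NULL
  class(ed) <- c("channel_edges", "data.frame")

  list(
    edges = ed,
    truth = list(
      hub_gene = hub,
      hub_cluster = c(star, tail_nodes),
      ribosomal_genes = ribo,
      decoy_edges = data.frame(gene_a = dec_a, gene_b = dec_b,
                               stringsAsFactors = FALSE)
    )
  )
}

#' Simulate a GMT gene-set collection with one planted enriched term
#'
#' Generates `n_terms` gene sets over the supplied universe. The first term is
#' planted: at least `planted_frac` of its members are drawn from
#' `planted_genes`, so a query consisting of those genes is strongly
#' over-represented in it. All remaining terms are uniform draws from the
#' universe.
#'
#' @param genes universe of gene symbols.
#' @param planted_genes genes to concentrate in the planted term.
#' @param n_terms total number of terms (including the planted one).
#' @param size_range inclusive range of term sizes.
#' @param planted_frac minimum fraction of the planted term drawn from
#'   `planted_genes` (default 0.9).
#' @param seed integer seed.
#'
#' @return list with `collection` (named list of member vectors, with a
#'   `descriptions` attribute) and `planted_term` (the term id).
#' @export
simulate_genesets <- function(genes, planted_genes, n_terms = 50,
                              size_range = c(10, 40), planted_frac = 0.9,
                              seed = 1) {
  genes <- unique(as.character(genes))
  planted_genes <- unique(as.character(planted_genes))
  if (size_range[2] > length(genes)) stop_input("universe smaller than 'size_range'")
  if (size_range[1] < 2 || size_range[1] > size_range[2]) {
    stop_input("'size_range' must be an increasing pair >= 2")
  }
  if (planted_frac < 0.8) stop_input("'planted_frac' must be >= 0.8")
  set.seed(seed)

  k_planted <- min(size_range[2], max(size_range[1], floor(length(planted_genes) / planted_frac)))
  n_from_planted <- ceiling(planted_frac * k_planted)
  if (n_from_planted > length(planted_genes)) {
    stop_input("not enough planted genes for the requested term size")
  }
  ids <- sprintf("TERM%04d", seq_len(n_terms))
  members <- vector("list", n_terms)
  members[[1L]] <- sort(c(sample(planted_genes, n_from_planted),
                          sample(setdiff(genes, planted_genes),
                                 k_planted - n_from_planted)))
  sizes <- sample(seq(size_range[1], size_range[2]), n_terms - 1L, replace = TRUE)
  for (i in seq_len(n_terms - 1L)) {
    members[[i + 1L]] <- sort(sample(genes, sizes[i]))
  }
  names(members) <- ids
  attr(members, "descriptions") <- stats::setNames(
    c("planted enriched term", rep("random term", n_terms - 1L)), ids)
  list(collection = members, planted_term = ids[1L])
}

#' @rdname write_synthetic
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Writers for the synthetic inputs
#'
#' Plain-text writers for the simulator outputs: count matrix TSV (first
#' column `gene`), two-column sample sheet, STRING detailed-dialect edge list
#' (integer scores 0-1000, historical column spelling `cooccurence`), GMT
#' gene sets, one-symbol-per-line gene lists, and a JSON truth sidecar.
#'
#' @param counts,samples,edges,collection,genes,truth objects from the
#'   simulators.
#' @param path output file path.
#' @name write_synthetic
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples[, c("sample", "group")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synthetic
#' @export
write_string_edges <- function(edges, path) {
  out <- data.frame(
    protein1 = edges$gene_a,
    protein2 = edges$gene_b,
    neighborhood = as.integer(round(edges$neighborhood * 1000)),
    fusion = as.integer(round(edges$fusion * 1000)),
    cooccurence = as.integer(round(edges$cooccurrence * 1000)),
    coexpression = as.integer(round(edges$coexpression * 1000)),
    experimental = as.integer(round(edges$experimental * 1000)),
    database = as.integer(round(edges$database * 1000)),
    textmining = as.integer(round(edges$textmining * 1000)),
    combined_score = as.integer(round(edges$combined_score * 1000))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_synthetic
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(id) {
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_synthetic
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' @rdname write_synthetic
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
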