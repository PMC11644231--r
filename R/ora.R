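#' Read a GMT gene-set file
#'
#' Each GMT line is `term<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a set are deduplicated; lines with fewer than
#' three fields or without any member raise an error naming the line.
#'
#' @param path GMT file path.
#' @return named list of member character vectors with a `descriptions`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  desc <- character(length(fields))
  ids <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop_input(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields", i))
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop_input(sprintf("malformed GMT line %d: empty gene set", i))
    }
    ids[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- members
  }
  if (anyDuplicated(ids)) stop_input("duplicate term ids in GMT file")
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(desc, ids)
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance. With background size N, set size K (after
#' intersection with the background), query size n, and overlap k, the
#' p-value is the upper-tail hypergeometric probability `P(X >= k)`, FDR is
#' Benjamini-Hochberg across all tested terms, and fold enrichment is
#' `(k/n) / (K/N)`. Query genes outside the background are dropped; sets
#' with no background member are skipped.
#'
#' @param query character vector of gene symbols (e.g. a DEG list).
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param background character vector: the gene universe.
#' @return data.frame with one row per tested term: `term`, `description`,
#'   `set_size`, `query_size`, `overlap`, `background`, `pvalue`, `fdr`,
#'   `fold_enrichment`.
#' @export
hypergeom_enrichment <- function(query, collection, background) {
  background <- unique(as.character(background))
  if (length(background) == 0L) stop_input("empty background")
  query <- unique(as.character(query))
  query <- query[query %in% background]
  if (length(query) == 0L) stop_input("empty query after background intersection")

  N <- length(background)
  n <- length(query)
  desc <- attr(collection, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(collection)), names(collection))

  sets <- lapply(collection, function(s) unique(s[s %in% background]))
  K <- lengths(sets)
  keep <- K > 0L
  sets <- sets[keep]
  K <- K[keep]
  k <- vapply(sets, function(s) sum(query %in% s), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)

  data.frame(
    term = names(sets),
    description = unname(desc[names(sets)]),
    set_size = as.integer(K),
    query_size = n,
    overlap = as.integer(k),
    background = N,
    pvalue = as.numeric(p),
    fdr = bh_adjust(as.numeric(p)),
    fold_enrichment = (k / n) / (K / N),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Ranked enrichment report
#'
#' Filters the enrichment table to significant terms (`fdr <= fdr_max`) and
#' sorts by fold enrichment descending, breaking ties by FDR ascending and
#' then term id — the "fold enrichment after FDR" ordering.
#'
#' @param records table from [hypergeom_enrichment()].
#' @param fdr_max FDR threshold (inclusive, default 0.05).
#' @return filtered, ordered data.frame with the same columns.
#' @export
enrich_report <- function(records, fdr_max = 0.05) {
  out <- records[records$fdr <= fdr_max, , drop = FALSE]
  out <- out[order(-out$fold_enrichment, out$fdr, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname write_synthetic
#' @export
write_enrichment_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
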