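#' A collection of gene sets over an analysis universe
#'
#' Restricts every set to the universe (the genes that survived
#' preprocessing and entered the statistics, not the whole genome) and
#' drops sets left empty, with a warning.
#'
#' @param sets named list of character vectors (set name -> member ids).
#' @param universe character vector of analyzable gene ids.
#' @return a `gene_set_collection` list with `sets` and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (anyDuplicated(universe)) stop("duplicate ids in universe")
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropping empty gene set(s) after restriction to universe: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, member genes, tab
#'   separated).
#' @param universe gene universe for [gene_set_collection()]; defaults to
#'   the union of all members.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe)
}

#' Write gene sets to a GMT file
#'
#' @param collection a `gene_set_collection` (or plain named list).
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(collection, path, description = "na") {
  sets <- if (inherits(collection, "gene_set_collection"))
    collection$sets else collection
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

hyper_tail <- function(k, K, n, N) {
  # P(X >= k) for X ~ Hypergeometric(N, K, n); exact log-space tail
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of gene sets in a cluster
#'
#' For each set, tests whether the cluster contains more set members
#' than expected under random draws from the universe:
#' p = P(X >= k), X ~ Hypergeometric(N, K, n) with N the universe size,
#' K the set size, n the cluster size and k the overlap. The enrichment
#' factor ef = (k/n)/(K/N) is reported alongside, with a per-collection
#' Bonferroni-adjusted p; `significant` applies `threshold` to the raw
#' p-value.
#'
#' @param cluster_genes gene ids of one cluster (subset of the universe).
#' @param collection a [gene_set_collection()].
#' @param threshold raw p-value cut-off (default 1e-6).
#' @return data.frame `set_name`, `k`, `n`, `K`, `N`, `ef`, `p`,
#'   `p_bonferroni`, `significant`.
#' @export
hypergeometric_enrichment <- function(cluster_genes, collection,
                                      threshold = 1e-6) {
  stopifnot(inherits(collection, "gene_set_collection"))
  cluster_genes <- unique(cluster_genes)
  outside <- setdiff(cluster_genes, collection$universe)
  if (length(outside))
    stop("cluster gene(s) outside the universe: ",
         paste(utils::head(outside, 10), collapse = ", "))
  N <- length(collection$universe)
  n <- length(cluster_genes)
  m <- length(collection$sets)
  res <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    K <- length(members)
    k <- length(intersect(cluster_genes, members))
    p <- hyper_tail(k, K, n, N)
    data.frame(set_name = nm, k = k, n = n, K = K, N = N,
               ef = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
               p = p, p_bonferroni = min(1, p * m),
               significant = p < threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Overlap of clusters with a reference gene set
#'
#' Applies the hypergeometric machinery cluster by cluster against a
#' single reference list (e.g. previously published glucose-responsive
#' genes), labelling clusters below the cut-off `NS`.
#'
#' @param clusters named list of gene-id vectors, or the `cluster`
#'   component of [kmeans_correlation()].
#' @param reference reference gene ids (restricted to the universe).
#' @param universe analyzable gene ids.
#' @param threshold raw p-value cut-off for significance (default 1e-6).
#' @return data.frame `cluster`, `k`, `n`, `K`, `N`, `ef`, `p`,
#'   `significant`, `label` (`"NS"` where not significant).
#' @export
overlap_with_reference <- function(clusters, reference, universe,
                                   threshold = 1e-6) {
  if (!is.list(clusters))
    clusters <- split(names(clusters), clusters)
  reference <- intersect(unique(reference), universe)
  if (length(reference) == 0)
    stop("reference is empty after restriction to the universe")
  coll <- gene_set_collection(list(reference = reference), universe)
  res <- lapply(names(clusters), function(cl) {
    r <- hypergeometric_enrichment(clusters[[cl]], coll, threshold)
    data.frame(cluster = cl, r[, c("k", "n", "K", "N", "ef", "p",
                                   "significant")],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$label <- ifelse(out$significant, sprintf("p=%.3g", out$p), "NS")
  out
}

IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

#' Scan promoters for a degenerate IUPAC motif
#'
#' Exact matching of an IUPAC pattern (e.g. `TCGTTYAG`, Y = C or T)
#' against each promoter, optionally on both strands. Ambiguity codes are
#' expanded in the pattern only; an `N` in a promoter sequence is treated
#' as an unknown base and never matches. A promoter is a hit when it
#' contains at least one match.
#'
#' @param promoters named character vector or `Biostrings::DNAStringSet`
#'   of promoter sequences (ids as names).
#' @param motif IUPAC pattern string.
#' @param scan_both_strands also match the reverse complement
#'   (default TRUE).
#' @return data.frame `gene_id`, `hits` (match count), `hit` (logical).
#' @export
scan_motif <- function(promoters, motif, scan_both_strands = TRUE) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, IUPAC_ALPHABET)
  if (length(bad))
    stop("invalid IUPAC character(s) in motif: ", paste(bad, collapse = ", "))
  if (!methods::is(promoters, "DNAStringSet"))
    promoters <- Biostrings::DNAStringSet(promoters)
  if (is.null(names(promoters))) stop("promoters must be named by gene id")
  counts <- Biostrings::vcountPattern(motif, promoters, fixed = "subject")
  if (scan_both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
    counts <- counts + Biostrings::vcountPattern(rc, promoters, fixed = "subject")
  }
  data.frame(gene_id = names(promoters), hits = counts, hit = counts >= 1,
             stringsAsFactors = FALSE)
}

#' Motif enrichment factor for a gene cluster
#'
#' EF = (fraction of cluster promoters with >= 1 motif hit) /
#' (fraction of universe promoters with a hit), the standard
#' binding-site enrichment factor. Significance is assessed by the
#' hypergeometric tail on hit counts (drawing the cluster from the
#' universe of promoters).
#'
#' @param cluster_genes gene ids of the cluster.
#' @param hits either a [scan_motif()] result or a named logical vector.
#' @param universe analyzable gene ids; hits must cover all of them.
#' @return list `ef`, `p`, `cluster_fraction`, `universe_fraction`,
#'   `k`, `n`, `K`, `N`, `undefined` (TRUE when no universe promoter has
#'   a hit, leaving EF undefined).
#' @export
motif_enrichment_factor <- function(cluster_genes, hits, universe) {
  if (is.data.frame(hits)) hits <- stats::setNames(hits$hit, hits$gene_id)
  missing <- setdiff(universe, names(hits))
  if (length(missing))
    stop("hit flags missing for ", length(missing), " universe gene(s)")
  cluster_genes <- unique(cluster_genes)
  if (length(setdiff(cluster_genes, universe)))
    stop("cluster genes must lie in the universe")
  N <- length(universe)
  K <- sum(hits[universe])
  n <- length(cluster_genes)
  k <- sum(hits[cluster_genes])
  if (K == 0)
    return(list(ef = NA_real_, p = 1, cluster_fraction = 0,
                universe_fraction = 0, k = k, n = n, K = K, N = N,
                undefined = TRUE))
  list(ef = (k / n) / (K / N), p = hyper_tail(k, K, n, N),
       cluster_fraction = k / n, universe_fraction = K / N,
       k = k, n = n, K = K, N = N, undefined = FALSE)
}
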