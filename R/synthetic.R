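#' Synthetic PSSM benchmark configuration
#'
#' The generator emulates the structure of a golden-standard PPI benchmark
#' (balanced interacting / non-interacting pairs) with a latent-cluster
#' model: each protein belongs to a latent functional cluster and carries
#' a latent 20-vector
#' \eqn{u = \delta \cdot c_{cluster} + w}, where the cluster centers
#' \eqn{c} and the per-protein term \eqn{w} are standard normal.
#' Interacting pairs are drawn within a cluster, non-interacting pairs
#' across clusters, so \code{separation} (\eqn{\delta}) tunes how
#' detectable the interaction signal is: at \eqn{\delta = 0} labels carry
#' no signal at all.  PSSM rows are integer-rounded normal draws centered
#' on \eqn{u} with sd \code{noise_sd}, clipped to the PSI-BLAST log-odds
#' range [-10, 12].
#'
#' @param n_proteins number of proteins (default 80).
#' @param n_pairs_per_class interacting and non-interacting pair count
#'   (default 250, i.e. 500 pairs, a desk-scale analogue of the balanced
#'   benchmark layout).
#' @param length_range integer (min, max) residue counts, default
#'   c(50, 120).
#' @param separation between-class separation \eqn{\delta \ge 0},
#'   default 3.
#' @param noise_sd per-residue score noise, default 2 (log-odds units).
#' @param n_clusters latent clusters, default 4.
#' @param seed integer seed; everything downstream is a deterministic
#'   function of (config, seed).
#' @param center_seed optional separate seed for the cluster centers; two
#'   configs sharing a \code{center_seed} but differing in \code{seed}
#'   yield disjoint "species" governed by the same latent interaction
#'   structure (the cross-species transfer scenario).  Defaults to
#'   \code{seed}.
#' @param id_prefix prefix for protein ids (default \code{"P"}); use
#'   distinct prefixes when mixing datasets.
#' @return A \code{"synthetic_config"} list.
#' @export
synthetic_config <- function(n_proteins = 80L, n_pairs_per_class = 250L,
                             length_range = c(50L, 120L), separation = 3,
                             noise_sd = 2, n_clusters = 4L, seed = 1L,
                             center_seed = NULL, id_prefix = "P") {
  stopifnot(n_proteins >= 2, n_pairs_per_class >= 1,
            length(length_range) == 2L, length_range[1L] >= 1,
            length_range[1L] <= length_range[2L],
            separation >= 0, noise_sd >= 0, n_clusters >= 2,
            n_clusters <= n_proteins)
  if (is.null(center_seed)) center_seed <- seed
  structure(list(n_proteins = as.integer(n_proteins),
                 n_pairs_per_class = as.integer(n_pairs_per_class),
                 length_range = as.integer(length_range),
                 separation = separation, noise_sd = noise_sd,
                 n_clusters = as.integer(n_clusters),
                 seed = as.integer(seed),
                 center_seed = as.integer(center_seed),
                 id_prefix = as.character(id_prefix)),
            class = "synthetic_config")
}

#' Generate synthetic proteins as PSSMs
#'
#' See \code{\link{synthetic_config}} for the generative model.  Proteins
#' are assigned to clusters round-robin; each \code{\link{pssm}} carries
#' its cluster index as attribute \code{"cluster"} for the pair sampler.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return Named list of \code{\link{pssm}} objects (ids \code{"P0001"},
#'   ...).
#' @export
generate_proteins <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  centers <- with_seed(config$center_seed,
                       matrix(rnorm(config$n_clusters * 20L),
                              config$n_clusters))
  with_seed(config$seed, {
    ids <- sprintf("%s%04d", config$id_prefix,
                   seq_len(config$n_proteins))
    cluster <- rep_len(seq_len(config$n_clusters), config$n_proteins)
    out <- vector("list", config$n_proteins)
    names(out) <- ids
    for (i in seq_len(config$n_proteins)) {
      u <- config$separation * centers[cluster[i], ] + rnorm(20L)
      lr <- config$length_range
      len <- lr[1L] + sample.int(lr[2L] - lr[1L] + 1L, 1L) - 1L
      m <- matrix(u, nrow = len, ncol = 20L, byrow = TRUE) +
        config$noise_sd * matrix(rnorm(len * 20L), len)
      m <- pmin(pmax(round(m), -10L), 12L)
      p <- pssm(m, ids[i])
      attr(p, "cluster") <- cluster[i]
      out[[i]] <- p
    }
    out
  })
}

#' Sample balanced interacting / non-interacting pairs
#'
#' Interacting (label 1) pairs are drawn uniformly without replacement
#' from the within-cluster protein pairs, non-interacting (label 0) pairs
#' from the cross-cluster pairs — mirroring the convention that proteins
#' from different subcellular compartments are taken as non-interacting
#' negatives.  Classes are exactly balanced and no pair is duplicated.
#'
#' @param proteins a \code{\link{generate_proteins}} result.
#' @param config the same \code{\link{synthetic_config}}.
#' @return A \code{\link{pair_dataset}}.
#' @export
generate_pairs <- function(proteins, config) {
  stopifnot(inherits(config, "synthetic_config"), length(proteins) >= 2L)
  cluster <- vapply(proteins, attr, integer(1), "cluster")
  ids <- names(proteins)
  cmb <- utils::combn(length(ids), 2L)
  same <- cluster[cmb[1L, ]] == cluster[cmb[2L, ]]
  n <- config$n_pairs_per_class
  if (sum(same) < n || sum(!same) < n)
    stop("requested ", n, " pairs per class but only ", sum(same),
         " within-cluster and ", sum(!same),
         " cross-cluster pairs exist; increase n_proteins")
  with_seed(config$seed + 1L, {
    pos <- sample(which(same), n)
    neg <- sample(which(!same), n)
    take <- c(pos, neg)
    pairs <- data.frame(id_a = ids[cmb[1L, take]],
                        id_b = ids[cmb[2L, take]],
                        label = rep(c(1L, 0L), each = n),
                        stringsAsFactors = FALSE)
    # interleave labels so file order carries no label structure
    pairs <- pairs[order(rep(seq_len(n), 2L), rep(c(1L, 2L), each = n)), ]
    rownames(pairs) <- NULL
    pair_dataset(pairs, proteins)
  })
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper: proteins plus balanced pairs, optionally written
#' to disk as one \code{<id>.pssm} file per protein (via
#' \code{\link{write_pssm}}) plus a \code{pairs.tsv} pair list, then read
#' back through the standard parsers so the full I/O path is exercised.
#' Byte-identical output for identical (config, seed).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param dir output directory; \code{NULL} (default) keeps everything in
#'   memory.
#' @return A \code{\link{pair_dataset}}.
#' @export
generate_synthetic_dataset <- function(config = synthetic_config(),
                                       dir = NULL) {
  proteins <- generate_proteins(config)
  dataset <- generate_pairs(proteins, config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(dataset$pssms))
      write_pssm(dataset$pssms[[id]], file.path(dir, paste0(id, ".pssm")))
    write_pair_list(dataset, file.path(dir, "pairs.tsv"))
    dataset <- read_pair_list(file.path(dir, "pairs.tsv"), dir)
  }
  dataset
}
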