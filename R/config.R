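#' Pipeline configuration
#'
#' Bundles the tunable parameters of the descriptor and classifier chain.
#'
#' @param d retained 2DPCA components (1..20); default 20, the full basis.
#' @param K number of disjoint feature subsets per Rotation Forest tree;
#'   default 20.
#' @param L number of trees in the ensemble; default 2.  K = 20, L = 2 is
#'   the grid-search optimum for PSSM/2DPCA pair descriptors.
#' @param bootstrap_fraction fraction of the class-subset samples drawn
#'   (without replacement) before the per-subset PCA; default 0.75.
#' @param class_subset_rule \code{"random"} (each class kept with
#'   probability 1/2, resampled while empty) or \code{"all"}.
#' @param fixed_transform how variable-length PSSMs are standardized:
#'   \code{"gram"} (default) or \code{"pad_truncate"}.
#' @param center center matrices by the training mean before projection.
#' @param sigmoid squash raw log-odds through a sigmoid first.
#' @param folds number of cross-validation folds; default 5.
#' @return A \code{"pipeline_config"} list.
#' @export
pipeline_config <- function(d = 20L, K = 20L, L = 2L,
                            bootstrap_fraction = 0.75,
                            class_subset_rule = c("random", "all"),
                            fixed_transform = c("gram", "pad_truncate"),
                            center = TRUE, sigmoid = FALSE, folds = 5L) {
  stopifnot(d >= 1, d <= 20, K >= 1, L >= 1,
            bootstrap_fraction > 0, bootstrap_fraction <= 1,
            folds >= 2)
  structure(list(d = as.integer(d), K = as.integer(K), L = as.integer(L),
                 bootstrap_fraction = bootstrap_fraction,
                 class_subset_rule = match.arg(class_subset_rule),
                 fixed_transform = match.arg(fixed_transform),
                 center = isTRUE(center), sigmoid = isTRUE(sigmoid),
                 folds = as.integer(folds)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("pipeline_config: d=%d, K=%d, L=%d, ",
                     "bootstrap_fraction=%.2f, %s transform, folds=%d\n"),
              x$d, x$K, x$L, x$bootstrap_fraction, x$fixed_transform,
              x$folds))
  invisible(x)
}
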