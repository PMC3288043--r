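#' Hierarchically cluster sample profiles or fold-change profiles
#'
#' Agglomerative clustering of the columns of a profile table under the
#' correlation distance `1 - Pearson(r)` with average linkage, as used for
#' expression and fold-change clustergrams. Distances to a zero-variance
#' column are undefined under the correlation metric and are set to 1 with a
#' warning.
#'
#' @param profiles For `input = "expression"`, a normalized long tibble from
#'   [normalize_log2()] (columns `mirna_id`, `sample_id`, `log2_intensity`);
#'   for `input = "fold_change"`, a fold-change tibble from [fold_changes()]
#'   (columns are then cell lines, values `log2_fc`).
#' @param input Which profile kind the columns represent.
#' @return An object of class `mir_cluster` wrapping the `hclust` tree, with
#'   elements `hclust`, `leaf_order` (labels in dendrogram order),
#'   `distance` tag and `input` kind.
#' @export
cluster_profiles <- function(profiles, input = c("expression", "fold_change")) {
  input <- match.arg(input)
  wide <- if (input == "expression") {
    tidyr::pivot_wider(profiles[, c("mirna_id", "sample_id", "log2_intensity")],
                       names_from = "sample_id", values_from = "log2_intensity")
  } else {
    tidyr::pivot_wider(profiles[, c("mirna_id", "cell_line", "log2_fc")],
                       names_from = "cell_line", values_from = "log2_fc")
  }
  mat <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(mat) < 2) {
    abort("Clustering needs at least two columns.", class = "mirscreen_design_error")
  }
  zero_var <- apply(mat, 2, stats::sd) == 0
  d <- 1 - suppressWarnings(cor(mat))
  if (any(zero_var)) {
    warn("Zero-variance column(s); correlation distance to them set to 1.")
    d[zero_var, ] <- 1
    d[, zero_var] <- 1
  }
  diag(d) <- 0
  tree <- hclust(as.dist(d), method = "average")
  structure(
    list(hclust = tree, leaf_order = tree$labels[tree$order],
         distance = "1 - Pearson correlation", input = input),
    class = "mir_cluster"
  )
}

#' @export
print.mir_cluster <- function(x, ...) {
  cat("<mir_cluster> ", length(x$leaf_order), " leaves, ", x$distance,
      ", average linkage (", x$input, " profiles)\n", sep = "")
  cat("  leaf order:", paste(x$leaf_order, collapse = ", "), "\n")
  invisible(x)
}

#' First merges of a cluster tree
#'
#' Convenience accessor returning, for each merge in height order, the
#' labels of the two leaves joined when both children are leaves. Used to
#' check that same-line treated/control pairs merge before any cross-line
#' pair.
#'
#' @param x A `mir_cluster`.
#' @return Tibble `height`, `label1`, `label2` (leaf-leaf merges only).
#' @export
leaf_merges <- function(x) {
  stopifnot(inherits(x, "mir_cluster"))
  m <- x$hclust$merge
  keep <- m[, 1] < 0 & m[, 2] < 0
  tibble(
    height = x$hclust$height[keep],
    label1 = x$hclust$labels[-m[keep, 1]],
    label2 = x$hclust$labels[-m[keep, 2]]
  )
}
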