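#' Scale a spot-size vector to unit Euclidean norm
#'
#' Divides a vector by its L2 norm, the normalization applied to
#' per-sample ELISPOT size vectors before overlaying their
#' distributions. Scale-invariant and idempotent.
#'
#' @param sizes Nonempty numeric vector, not all zero.
#' @return Vector with Euclidean norm 1.
#' @examples
#' unit_norm(c(3, 4)) # c(0.6, 0.8)
#' @export
unit_norm <- function(sizes) {
  stopifnot(is.numeric(sizes), length(sizes) >= 1, all(is.finite(sizes)))
  nrm <- sqrt(sum(sizes^2))
  if (nrm == 0) stop("cannot normalize the zero vector")
  sizes / nrm
}

# Scott's rule of thumb, as used by the common KDE plotting stacks:
# bw = sd(x) * n^(-1/5).
bw_scott <- function(x) stats::sd(x) * length(x)^(-1 / 5)

#' Gaussian kernel density estimate of a spot-size distribution
#'
#' Evaluates a Gaussian KDE on a grid. The default bandwidth is Scott's
#' rule (`sd * n^(-1/5)`); Silverman's rule or a fixed numeric bandwidth
#' may be substituted. The default grid spans the data plus three
#' bandwidths on each side, over which the estimate integrates to 1
#' (within quadrature error).
#'
#' @param sizes Numeric vector with >= 2 distinct values.
#' @param grid Optional evaluation grid; default 512 equispaced points
#'   spanning `range(sizes)` plus/minus 3 bandwidths.
#' @param bandwidth_rule `"scott"` (default) or `"silverman"`.
#' @param bw Optional fixed numeric bandwidth overriding the rule.
#' @return Data frame with columns `x` and `density`; the bandwidth used
#'   is attached as attribute `"bw"`.
#' @export
kde_curve <- function(sizes, grid = NULL,
                      bandwidth_rule = c("scott", "silverman"), bw = NULL) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  stopifnot(is.numeric(sizes), all(is.finite(sizes)))
  if (length(unique(sizes)) < 2) {
    stop("KDE requires >= 2 distinct values (bandwidth would be zero)")
  }
  if (is.null(bw)) {
    bw <- switch(bandwidth_rule,
                 scott = bw_scott(sizes),
                 silverman = stats::bw.nrd0(sizes))
  }
  stopifnot(is.numeric(bw), bw > 0)
  if (is.null(grid)) {
    grid <- seq(min(sizes) - 3 * bw, max(sizes) + 3 * bw, length.out = 512)
  }
  dens <- numeric(length(grid))
  # chunked accumulation keeps memory flat for large samples
  idx <- split(seq_along(sizes), ceiling(seq_along(sizes) / 2000))
  for (ii in idx) {
    dens <- dens + rowSums(stats::dnorm(outer(grid, sizes[ii], "-") / bw))
  }
  structure(data.frame(x = grid, density = dens / (length(sizes) * bw)),
            bw = bw)
}

#' Compare mean spot size between two groups of subjects
#'
#' Reduces each subject's spot-size vector to its mean and compares the
#' per-subject means (never the pooled spots, which would treat spots as
#' independent subjects) between conditions: a paired t test when the
#' groups are matched by subject (e.g. same donors with and without
#' hIL-6), Welch's t otherwise. Raw sizes are used: unit-norm scaling is
#' for distribution overlays and destroys between-sample mean
#' information.
#'
#' @param a,b Lists of [spot_size_sample()] objects.
#' @param paired If `TRUE`, subjects must match one-to-one (pairing by
#'   `subject_id`).
#' @param sidedness `"two"` or `"one"`, passed to the underlying test.
#' @return A `group_comparison`.
#' @export
compare_mean_spot <- function(a, b, paired = FALSE,
                              sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  stopifnot(is.list(a), is.list(b),
            all(vapply(a, inherits, logical(1), "spot_size_sample")),
            all(vapply(b, inherits, logical(1), "spot_size_sample")))
  mean_a <- vapply(a, function(s) mean(s$sizes), numeric(1))
  mean_b <- vapply(b, function(s) mean(s$sizes), numeric(1))
  if (paired) {
    ids_a <- vapply(a, `[[`, character(1), "subject_id")
    ids_b <- vapply(b, `[[`, character(1), "subject_id")
    if (length(ids_a) != length(ids_b) || !setequal(ids_a, ids_b) ||
        anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
      stop("paired comparison requires matching subject_ids in both groups")
    }
    mean_b <- mean_b[match(ids_a, ids_b)]
    paired_t(mean_a, mean_b, sidedness = sidedness)
  } else {
    welch_t(mean_a, mean_b, sidedness = sidedness)
  }
}

#' Per-cell antibody secretion rate
#'
#' Bulk secretion rate from an ELISA/cell-count pairing: total secreted
#' IgG divided by cell number and collection interval, in pg/cell/day.
#'
#' @param total_igg Total IgG secreted over the interval (pg), >= 0.
#' @param n_cells Number of secreting cells, > 0.
#' @param interval Collection interval (days), > 0.
#' @return Rate in pg/cell/day.
#' @examples
#' per_cell_secretion_rate(5000, 100, 1) # 50 pg/cell/day
#' @export
per_cell_secretion_rate <- function(total_igg, n_cells, interval) {
  stopifnot(is.numeric(total_igg), is.numeric(n_cells), is.numeric(interval))
  if (any(total_igg < 0)) stop("total_igg must be nonnegative")
  if (any(n_cells <= 0) || any(interval <= 0)) {
    stop("n_cells and interval must be positive")
  }
  total_igg / (n_cells * interval)
}
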