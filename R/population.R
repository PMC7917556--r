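## Population-level assembly: cell-ellipse geometry and pillar-modiolar
## positions, the per-synapse profile table, correlations, K-means
## phenotyping, PCA, and group statistics.

#' The default clustering property set
#'
#' The eleven per-synapse properties used for correlation, K-means and PCA:
#' voltage dependence of synaptic calcium influx (`v_half_ca`, `k_ca`,
#' `v10_ca`, `dr_ca`), peak calcium signal (`peak_rhod`), voltage dependence
#' of glutamate release (`v_half_rel`, `k_rel`, `v10_rel`, `dr_rel`), maximum
#' release (`max_auc_rel`) and calcium cooperativity (`m`). Positional and
#' whole-cell information is deliberately not part of the set.
#' @export
clustering_properties <- c("v_half_ca", "k_ca", "v10_ca", "dr_ca",
                           "peak_rhod", "v_half_rel", "k_rel", "v10_rel",
                           "dr_rel", "max_auc_rel", "m")

#' Fit the cell-boundary ellipse to a baseline image
#'
#' Otsu-thresholds the baseline fluorescence, keeps the largest connected
#' component and fits an ellipse by the second-moment method (semi-axes =
#' 2 sqrt(eigenvalues) of the pixel covariance). The major axis defines the
#' pillar-modiolar axis; which end is the pillar side is a recording-side
#' configuration, not an image property.
#'
#' @param baseline_image numeric matrix.
#' @param pillar which side of the image the pillar vertex faces: `"left"`,
#'   `"right"`, `"top"`, `"bottom"`.
#' @return object of class `cell_ellipse`: `center` (x, y), `semi_major`,
#'   `semi_minor`, `angle_rad` (major axis vs x-axis, in (-pi/2, pi/2]),
#'   `pillar_vertex` (x, y), `modiolar_vertex`, `degenerate` flag.
#' @export
fit_cell_ellipse <- function(baseline_image,
                             pillar = c("left", "right", "top", "bottom")) {
  pillar <- match.arg(pillar)
  img <- as.matrix(baseline_image)
  rng <- range(img)
  if (diff(rng) == 0) stop("segmentation error: constant image")
  scaled <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled))
  mask <- scaled > thr
  if (!any(mask)) stop("segmentation error: empty mask")
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  px <- which(lab == big, arr.ind = TRUE)       # (row, col) = (y, x)
  xy <- cbind(x = px[, 2], y = px[, 1])
  ctr <- colMeans(xy)
  cv <- stats::cov(xy) * (nrow(xy) - 1) / nrow(xy)
  eg <- eigen(cv, symmetric = TRUE)
  a <- 2 * sqrt(eg$values[1]); b <- 2 * sqrt(eg$values[2])
  degenerate <- (a - b) / a < 0.02
  ang <- if (degenerate) 0 else atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  if (ang > pi / 2) ang <- ang - pi
  if (ang <= -pi / 2) ang <- ang + pi
  axis_dir <- c(cos(ang), sin(ang))
  v1 <- ctr + a * axis_dir
  v2 <- ctr - a * axis_dir
  pick_pillar <- switch(pillar,
    left = if (v1[1] < v2[1]) v1 else v2,
    right = if (v1[1] > v2[1]) v1 else v2,
    top = if (v1[2] < v2[2]) v1 else v2,
    bottom = if (v1[2] > v2[2]) v1 else v2)
  other <- if (identical(pick_pillar, v1)) v2 else v1
  structure(list(center = c(x = unname(ctr[1]), y = unname(ctr[2])),
                 semi_major = a, semi_minor = b, angle_rad = ang,
                 pillar_vertex = c(x = pick_pillar[1], y = pick_pillar[2]),
                 modiolar_vertex = c(x = other[1], y = other[2]),
                 degenerate = degenerate),
            class = "cell_ellipse")
}

#' Position of a hot spot along the pillar-modiolar axis
#'
#' Orthogonally projects the hot-spot center onto the major axis (the
#' shortest-distance foot point) and returns its normalized coordinate
#' between the pillar vertex (0) and the modiolar vertex (1), clipped to
#' `[0, 1]`.
#'
#' @param ellipse a `cell_ellipse` (or a list with `pillar_vertex` and
#'   `modiolar_vertex`).
#' @param hotspot_xy numeric length-2 `(x, y)`.
#' @return scalar position in `[0, 1]`.
#' @export
axis_position <- function(ellipse, hotspot_xy) {
  p <- as.numeric(ellipse$pillar_vertex)
  q <- as.numeric(ellipse$modiolar_vertex)
  d <- q - p
  tt <- sum((as.numeric(hotspot_xy) - p) * d) / sum(d * d)
  min(max(tt, 0), 1)
}

#' Assemble the per-synapse profile table
#'
#' One row per synapse holding the clustering properties, the axis position,
#' and QC flags. Rows with any missing property or a fit flagged excluded
#' (R^2 gate) carry `qc_pass = FALSE` and are left out of clustering and PCA.
#'
#' @param profiles data.frame (or list of rows) with columns `cell_id`,
#'   `synapse_id`, the properties of [clustering_properties], `position_01`,
#'   and optionally `excluded` (logical, from the fits).
#' @return data.frame of class `synapse_profile_table` with added `qc_pass`,
#'   `cluster` (NA until assigned).
#' @export
build_table <- function(profiles) {
  df <- as.data.frame(profiles)
  if (nrow(df) == 0) {
    df <- data.frame(cell_id = character(), synapse_id = character())
    for (p in clustering_properties) df[[p]] <- numeric()
    df$position_01 <- numeric(); df$qc_pass <- logical()
    df$cluster <- integer()
    class(df) <- c("synapse_profile_table", "data.frame")
    return(df)
  }
  key <- paste(df$cell_id, df$synapse_id, sep = "/")
  if (anyDuplicated(key))
    stop("integrity error: duplicate synapse id ",
         key[duplicated(key)][1])
  missing_prop <- setdiff(clustering_properties, names(df))
  if (length(missing_prop) > 0)
    stop("missing properties: ", paste(missing_prop, collapse = ", "))
  excl <- if ("excluded" %in% names(df)) df$excluded else FALSE
  complete <- stats::complete.cases(df[, clustering_properties])
  df$qc_pass <- complete & !excl
  if (!"cluster" %in% names(df)) df$cluster <- NA_integer_
  class(df) <- c("synapse_profile_table", "data.frame")
  df
}

#' Pearson correlation matrix of synapse properties
#'
#' Pairwise-complete Pearson correlations over the QC-passing rows;
#' zero-variance properties yield NA with a warning.
#'
#' @param table a [build_table()] result.
#' @param properties columns to correlate (default the clustering set plus
#'   position).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlate_properties <- function(table,
                                 properties = c(clustering_properties,
                                                "position_01")) {
  df <- table[table$qc_pass, properties, drop = FALSE]
  if (nrow(df) < 3) stop("need >= 3 complete rows")
  sds <- vapply(df, stats::sd, numeric(1))
  if (any(sds == 0))
    warning("zero-variance properties reported as NA: ",
            paste(names(sds)[sds == 0], collapse = ", "))
  suppressWarnings(stats::cor(as.matrix(df), use = "pairwise.complete.obs",
                              method = "pearson"))
}

#' K-means phenotyping of synapses
#'
#' Z-scores the clustering properties over the QC-passing rows, runs K-means
#' (k-means++-style seeding via many restarts) and relabels the clusters by
#' ascending centroid cooperativity m, so that cluster 1 is the
#' lowest-cooperativity (nanodomain-like) subtype regardless of seed.
#'
#' @param table a [build_table()] result.
#' @param K number of clusters (default 3).
#' @param seed integer seed.
#' @param nstart random restarts (default 25).
#' @return list with `table` (input with `cluster` filled for QC-passing
#'   rows), `centers` (z-score space, rows ordered by m), `sizes`,
#'   `tot_withinss`.
#' @export
cluster_synapses <- function(table, K = 3, seed = 1L, nstart = 25) {
  ok <- which(table$qc_pass)
  if (length(ok) < K) stop("clustering error: fewer complete rows than K")
  z <- scale(as.matrix(table[ok, clustering_properties]))
  z[, attr(z, "scaled:scale") == 0] <- 0
  km <- withr::with_seed(seed,
    stats::kmeans(z, centers = K, nstart = nstart, iter.max = 100))
  ord <- order(km$centers[, "m"])
  relab <- match(seq_len(K), ord)
  new_lab <- relab[km$cluster]
  table$cluster <- NA_integer_
  table$cluster[ok] <- new_lab
  list(table = table,
       centers = km$centers[ord, , drop = FALSE],
       sizes = tabulate(new_lab, nbins = K),
       tot_withinss = km$tot.withinss)
}

#' PCA of the synapse-property space
#'
#' Principal component analysis of the z-scored clustering properties of the
#' QC-passing rows.
#'
#' @param table a [build_table()] result.
#' @param n_components components to return (default all).
#' @return list with `scores`, `loadings`, `explained` (variance ratios,
#'   descending, summing to 1).
#' @export
pca_project <- function(table, n_components = NULL) {
  ok <- table$qc_pass
  if (sum(ok) < 3) stop("need >= 3 complete rows")
  x <- as.matrix(table[ok, clustering_properties])
  if (all(apply(x, 2, stats::sd) == 0)) stop("degenerate: constant table")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(n_components)) length(expl) else n_components
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)],
       explained_all = expl)
}

#' D'Agostino & Pearson omnibus normality test
#'
#' Combines the standardized skewness and kurtosis statistics into
#' `K2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2 degrees
#' of freedom (D'Agostino, Belanger & D'Agostino 1990).
#'
#' @param x numeric sample (n >= 8; the kurtosis normalization is unstable
#'   below that).
#' @return list with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("need n >= 8")
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - e_b2) / sqrt(var_b2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a_k <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * a_k)) -
           ((1 - 2 / a_k) / (1 + xk * sqrt(2 / (a_k - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a_k))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2,
                                               lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Compare synapse groups property by property
#'
#' Splits the QC-passing synapses at a position threshold (pillar vs modiolar
#' halves) or by cluster label, and tests each property: groups are checked
#' for normality (D'Agostino-Pearson omnibus, alpha 0.05), then compared by
#' an unpaired two-sided t-test when both pass, otherwise by a Mann-Whitney
#' U-test; dispersion is compared by Levene's test. With more than two groups
#' (cluster mode) a one-way ANOVA with post hoc Tukey HSD is run instead.
#'
#' @param table a [build_table()] result.
#' @param by `"position"` or `"cluster"`.
#' @param split position threshold (default 0.5) for `by = "position"`.
#' @param properties properties to test.
#' @param alpha normality-gate level.
#' @return data.frame with one row per property (and per pair for Tukey):
#'   test used, statistic, p-value, group sizes; rows for groups smaller than
#'   3 are flagged skipped.
#' @export
compare_groups <- function(table, by = c("position", "cluster"), split = 0.5,
                           properties = clustering_properties, alpha = 0.05) {
  by <- match.arg(by)
  df <- table[table$qc_pass, , drop = FALSE]
  grp <- if (by == "position") {
    factor(ifelse(df$position_01 <= split, "pillar", "modiolar"),
           levels = c("pillar", "modiolar"))
  } else {
    factor(df$cluster)
  }
  if (nlevels(droplevels(grp)) < 2)
    stop("need at least two non-empty groups")
  res <- list()
  for (p in properties) {
    x <- df[[p]]
    sizes <- tabulate(grp)
    if (any(sizes < 3)) {
      res[[length(res) + 1]] <- data.frame(
        property = p, comparison = "all", test = "skipped",
        statistic = NA_real_, p_value = NA_real_,
        n = paste(sizes, collapse = "/"),
        stringsAsFactors = FALSE)
      next
    }
    if (nlevels(grp) == 2) {
      g1 <- x[grp == levels(grp)[1]]; g2 <- x[grp == levels(grp)[2]]
      normal <- tryCatch(
        dagostino_pearson(g1)$p_value > alpha &&
          dagostino_pearson(g2)$p_value > alpha,
        error = function(e) FALSE)   # small n: no normality evidence
      loc <- if (normal) {
        tt <- stats::t.test(g1, g2)
        c(test = "t", stat = unname(tt$statistic), p = tt$p.value)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(g1, g2))
        c(test = "mann-whitney", stat = unname(wt$statistic), p = wt$p.value)
      }
      lev <- car::leveneTest(x ~ grp)
      res[[length(res) + 1]] <- data.frame(
        property = p,
        comparison = paste(levels(grp), collapse = " vs "),
        test = c(loc[["test"]], "levene"),
        statistic = as.numeric(c(loc[["stat"]], lev$`F value`[1])),
        p_value = as.numeric(c(loc[["p"]], lev$`Pr(>F)`[1])),
        n = paste(sizes, collapse = "/"),
        stringsAsFactors = FALSE)
    } else {
      av <- stats::aov(x ~ grp)
      sm <- summary(av)[[1]]
      tk <- stats::TukeyHSD(av)$grp
      rows <- data.frame(
        property = p,
        comparison = c("anova", rownames(tk)),
        test = c("anova", rep("tukey", nrow(tk))),
        statistic = c(sm$`F value`[1], tk[, "diff"]),
        p_value = c(sm$`Pr(>F)`[1], tk[, "p adj"]),
        n = paste(sizes, collapse = "/"),
        stringsAsFactors = FALSE)
      res[[length(res) + 1]] <- rows
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
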