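adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

test_that("second-moment ellipse fits recover synthetic cell outlines", {
  # filled ellipse a=100, b=40 at 30 degrees in a 300x300 frame
  nx <- ny <- 300
  xs <- matrix(rep(1:nx, each = ny), ny, nx)
  ys <- matrix(rep(1:ny, nx), ny, nx)
  th <- 30 * pi / 180
  u <- (xs - 150) * cos(th) + (ys - 150) * sin(th)
  v <- -(xs - 150) * sin(th) + (ys - 150) * cos(th)
  img <- 10 + 90 * ((u / 100)^2 + (v / 40)^2 <= 1)
  ell <- fit_cell_ellipse(img, pillar = "left")
  expect_equal(ell$semi_major, 100, tolerance = 0.02)
  expect_equal(ell$semi_minor, 40, tolerance = 0.02)
  expect_equal(ell$angle_rad, th, tolerance = 0.02)
  expect_equal(unname(ell$center), c(150, 150), tolerance = 0.01)
  expect_false(ell$degenerate)
  # a circle has no defined axis: degenerate flag, angle 0
  imgc <- 10 + 90 * (((xs - 150)^2 + (ys - 150)^2) <= 70^2)
  ellc <- fit_cell_ellipse(imgc)
  expect_true(ellc$degenerate)
  expect_equal(ellc$angle_rad, 0)
  expect_error(fit_cell_ellipse(matrix(1, 50, 50)), "segmentation error")
})

test_that("the rendered cell baseline yields the generator ellipse", {
  cc <- small_cell()
  rhod <- cc$cell$rhod
  baseline <- apply(rhod$movies[[3]][, , 1:15], c(1, 2), mean)
  ell <- fit_cell_ellipse(baseline, pillar = "left")
  truth <- cc$cell$gt$ellipse
  expect_lt(sqrt(sum((ell$center - c(truth$center[["x"]],
                                     truth$center[["y"]]))^2)), 2)
  expect_equal(ell$semi_major, truth$semi_major, tolerance = 0.15)
})

test_that("axis positions follow the orthogonal projection onto the major axis", {
  ell <- list(pillar_vertex = c(10, 50), modiolar_vertex = c(90, 50))
  expect_equal(axis_position(ell, c(50, 50)), 0.5)
  expect_equal(axis_position(ell, c(10, 50)), 0)
  expect_equal(axis_position(ell, c(90, 50)), 1)
  expect_equal(axis_position(ell, c(50, 80)), 0.5)   # off-axis projects back
  expect_equal(axis_position(ell, c(-20, 50)), 0)    # clipped
  # brute-force oracle: nearest point on a densely sampled axis segment
  set.seed(31)
  for (i in 1:20) {
    p <- runif(2, 0, 100); q <- runif(2, 0, 100)
    h <- runif(2, 0, 100)
    e2 <- list(pillar_vertex = p, modiolar_vertex = q)
    tt <- seq(0, 1, length.out = 20001)
    seg <- cbind(p[1] + tt * (q[1] - p[1]), p[2] + tt * (q[2] - p[2]))
    nearest <- tt[which.min((seg[, 1] - h[1])^2 + (seg[, 2] - h[2])^2)]
    # compare foot points in px (0.1 px tolerance)
    len <- sqrt(sum((q - p)^2))
    expect_lt(abs(axis_position(e2, h) - nearest) * len, 0.1)
  }
})

test_that("axis positions are invariant under rigid motions", {
  set.seed(37)
  p <- c(20, 30); q <- c(80, 55); h <- c(47, 60)
  base <- axis_position(list(pillar_vertex = p, modiolar_vertex = q), h)
  for (i in 1:10) {
    th <- runif(1, 0, 2 * pi); sh <- runif(2, -50, 50)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    mv <- function(x) as.numeric(R %*% x + sh)
    got <- axis_position(list(pillar_vertex = mv(p), modiolar_vertex = mv(q)),
                         mv(h))
    expect_equal(got, base, tolerance = 1e-12)
  }
})

test_that("the profile table enforces integrity and QC flags", {
  tab <- make_profile_table(c(2, 2, 2))
  expect_s3_class(tab, "synapse_profile_table")
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$qc_pass))
  # excluded fits are kept but flagged
  df <- as.data.frame(tab)
  df$excluded <- c(TRUE, rep(FALSE, 5))
  tab2 <- build_table(df)
  expect_false(tab2$qc_pass[1])
  expect_true(all(tab2$qc_pass[-1]))
  # missing property value
  df3 <- as.data.frame(tab); df3$m[2] <- NA; df3$excluded <- NULL
  expect_false(build_table(df3)$qc_pass[2])
  # duplicate synapse ids
  df4 <- rbind(as.data.frame(tab), as.data.frame(tab)[1, ])
  expect_error(build_table(df4), "integrity error")
  # empty input keeps a valid schema
  empty <- build_table(data.frame())
  expect_equal(nrow(empty), 0)
  expect_true(all(clustering_properties %in% names(empty)))
})

test_that("Pearson correlation matches the direct covariance formula", {
  tab <- make_profile_table(c(8, 8, 8), seed = 3)
  cm <- correlate_properties(tab)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  # direct formula oracle on the underlying columns
  df <- as.data.frame(tab)[, c(clustering_properties, "position_01")]
  for (i in c(1, 5)) for (j in c(3, 11)) {
    x <- df[[i]]; y <- df[[j]]
    r_oracle <- mean((x - mean(x)) * (y - mean(y))) /
      (sd(x) * sd(y)) * length(x) / (length(x) - 1)
    expect_equal(cm[i, j], r_oracle, tolerance = 1e-12)
  }
  # duplicated and negated columns
  df2 <- as.data.frame(tab)
  df2$k_ca <- df2$v_half_ca
  df2$k_rel <- -df2$v_half_ca
  tab2 <- build_table(df2)
  cm2 <- correlate_properties(tab2)
  expect_equal(cm2["v_half_ca", "k_ca"], 1)
  expect_equal(cm2["v_half_ca", "k_rel"], -1)
  # zero-variance column reported missing
  df3 <- as.data.frame(tab); df3$dr_ca <- 5
  expect_warning(cm3 <- correlate_properties(build_table(df3)),
                 "zero-variance")
  expect_true(is.na(cm3["dr_ca", "v_half_ca"]))
})

test_that("K-means phenotyping separates planted subtypes and orders them by m", {
  tab <- make_profile_table(c(12, 10, 8), sep = 10, seed = 5)
  cl <- cluster_synapses(tab, K = 3, seed = 1)
  expect_equal(adjusted_rand(cl$table$cluster, tab$true_group), 1.0)
  # relabeling by centroid m makes labels match the planted order
  means <- as.numeric(tapply(cl$table$m, cl$table$cluster, mean))
  expect_false(is.unsorted(means))
  # stable across seeds on separable data
  labs <- lapply(1:10, function(s) cluster_synapses(tab, K = 3, seed = s)$table$cluster)
  for (l in labs[-1]) expect_identical(l, labs[[1]])
  # invariant to row order after relabeling
  perm <- sample(nrow(tab))
  cl2 <- cluster_synapses(tab[perm, ], K = 3, seed = 1)
  expect_identical(cl2$table$cluster, cl$table$cluster[perm])
  # degenerate cases
  cl1 <- cluster_synapses(tab, K = 1, seed = 1)
  expect_true(all(cl1$table$cluster == 1))
  expect_error(cluster_synapses(tab[1:2, ], K = 3), "clustering error")
})

test_that("PCA explained-variance ratios behave as expected", {
  # rank-1 table: first component explains everything
  base <- make_profile_table(c(10))
  df <- as.data.frame(base)
  v <- seq_len(nrow(df))
  for (p in clustering_properties) df[[p]] <- v * runif(1, 0.5, 2)
  tab1 <- build_table(df)
  pc1 <- pca_project(tab1)
  expect_equal(pc1$explained[1], 1, tolerance = 1e-9)
  # ratios sum to one
  tab <- make_profile_table(c(10, 10, 10), seed = 7)
  pc <- pca_project(tab)
  expect_equal(sum(pc$explained_all), 1, tolerance = 1e-12)
  # isotropic data: each ratio near 1/11
  set.seed(8)
  dfi <- as.data.frame(make_profile_table(c(10)))[rep(1, 500), ]
  dfi$synapse_id <- 1:500
  for (p in clustering_properties) dfi[[p]] <- rnorm(500)
  pci <- pca_project(build_table(dfi))
  expect_true(all(abs(pci$explained_all - 1 / 11) < 0.05))
})

test_that("the omnibus normality statistic matches an independent reference", {
  # frozen reference values from an independent implementation
  x1 <- c(0.00123,0.298746,-0.274138,-0.890592,-0.454671,-0.991647,0.060144,
          1.340215,-0.492207,-0.620475,0.489842,0.356887,0.105414,-0.930468,
          -0.029252,0.695303,-1.344215,-0.457616,-1.901223,-1.289538,
          -1.841735,-0.235091,-1.267446,0.271264,0.156751,-0.186931,-2.51676,
          -0.538693,-0.048501,0.113309,-1.530136,-0.477753,-0.978519,
          -0.808837,1.060899,-0.807535,-0.032522,0.88439,-0.5836,-0.111702)
  x2 <- c(3.074857,1.404422,3.795412,1.748099,2.243039,0.144947,0.302554,
          0.238774,1.148245,1.223253,0.127217,0.383855,1.067887,0.068701,
          0.098201,0.871409,1.874,2.696352,0.706095,1.306072,0.763546,
          0.937058,0.144847,2.494997,0.884279,0.875212,0.026353,1.085041,
          1.061857,1.064204,0.568831,1.363631,1.573667,0.650021,0.35114)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 1.0883429528, tolerance = 1e-8)
  expect_equal(r1$p_value, 0.5803223950, tolerance = 1e-8)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 10.2428819209, tolerance = 1e-8)
  expect_equal(r2$p_value, 0.0059674179, tolerance = 1e-8)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("group comparisons gate the test choice on normality", {
  # identical groups: location tests are far from significant
  tab <- make_profile_table(c(15, 15), sep = 0, seed = 9)
  rep1 <- compare_groups(tab, by = "position", split = 0.5)
  loc <- rep1[rep1$test %in% c("t", "mann-whitney"), ]
  expect_true(all(loc$p_value > 0.05, na.rm = TRUE))
  # two normal groups shifted by 5 SD: t-test chosen and highly significant
  set.seed(10)
  df <- as.data.frame(make_profile_table(c(30, 30), sep = 0, seed = 10))
  grp_hi <- df$position_01 > 0.5
  df$v_half_ca <- rnorm(60) + ifelse(grp_hi, 5, 0)
  rep2 <- compare_groups(build_table(df), by = "position",
                         properties = "v_half_ca")
  row_t <- rep2[rep2$test %in% c("t", "mann-whitney"), ]
  expect_equal(row_t$test, "t")
  expect_lt(row_t$p_value, 0.001)
  # heavy-tailed data routes to Mann-Whitney
  df$v_half_ca <- rcauchy(60) + ifelse(grp_hi, 50, 0)
  rep3 <- compare_groups(build_table(df), by = "position",
                         properties = "v_half_ca")
  row_c <- rep3[rep3$test %in% c("t", "mann-whitney"), ]
  expect_equal(row_c$test, "mann-whitney")
  # cluster mode: ANOVA + Tukey rows
  tab3 <- make_profile_table(c(10, 10, 10), sep = 6, seed = 11)
  cl <- cluster_synapses(tab3, K = 3, seed = 1)
  rep4 <- compare_groups(cl$table, by = "cluster", properties = "m")
  expect_true("anova" %in% rep4$test)
  expect_equal(sum(rep4$test == "tukey"), 3)
})
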