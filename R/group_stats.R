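# Group statistics: normality/homogeneity gating, Kruskal-Wallis with
# Bonferroni-corrected rank-based post hocs (behavioral scalars and network
# metrics), edge-wise one-way ANOVA with Bonferroni over all edges (PEC
# features), and the 68 -> 7 lobe-level grouping used for reporting
# significant-edge counts.

#' Shapiro-Wilk and Levene screening per feature
#'
#' Shapiro-Wilk normality per group per feature and Levene's test (mean
#' centred, the classical form) across groups; a feature is flagged
#' `parametric` when no group rejects normality at `alpha` and variances are
#' homogeneous. Constant features are flagged non-parametric (normality is
#' undefined there).
#'
#' @param values Subjects x features numeric matrix (or vector for one
#'   feature).
#' @param group Factor of group labels, one per subject.
#' @param alpha Gate level, default 0.05.
#' @return Data frame with per-feature columns `shapiro_min_p`, `levene_p`,
#'   `parametric`.
#' @export
normality_and_homogeneity <- function(values, group, alpha = 0.05) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  group <- factor(group)
  stopifnot(nrow(values) == length(group))
  if (min(table(group)) < 3L) stop("need at least 3 observations per group")
  res <- lapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    sw <- vapply(levels(group), function(g) {
      x <- v[group == g]
      if (stats::sd(x) == 0) return(NA_real_)
      stats::shapiro.test(x)$p.value
    }, numeric(1))
    if (anyNA(sw))
      return(data.frame(shapiro_min_p = NA_real_, levene_p = NA_real_,
                        parametric = FALSE))
    lv <- car::leveneTest(v ~ group, center = mean)[["Pr(>F)"]][1L]
    data.frame(shapiro_min_p = min(sw), levene_p = lv,
               parametric = min(sw) > alpha && lv > alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- colnames(values)
  out
}

#' Kruskal-Wallis test with Bonferroni pairwise post hocs
#'
#' Omnibus H (tie-corrected, via [stats::kruskal.test()]); pairwise
#' Wilcoxon rank-sum comparisons with p-values multiplied by the number of
#' group pairs and capped at 1.
#'
#' @param values Numeric vector, one value per subject.
#' @param group Factor of group labels.
#' @return List with `H`, `p`, `post_hoc` (data frame: pair, p_raw,
#'   p_bonferroni), `test = "kruskal-wallis"`.
#' @export
kruskal_wallis_with_posthoc <- function(values, group) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  keep <- is.finite(values)
  values <- values[keep]
  group <- droplevels(group[keep])
  if (nlevels(group) < 2L || length(values) < 3L)
    return(list(H = NA_real_, p = NA_real_, post_hoc = NULL,
                test = "kruskal-wallis"))
  if (stats::sd(values) == 0) {
    kw <- list(statistic = c(H = 0), p.value = 1)
  } else {
    kw <- stats::kruskal.test(values, group)
  }
  lv <- levels(group)
  pairs <- utils::combn(lv, 2L)
  n_pairs <- ncol(pairs)
  ph <- data.frame(pair = apply(pairs, 2L, paste, collapse = "/"),
                   p_raw = NA_real_, p_bonferroni = NA_real_)
  for (k in seq_len(n_pairs)) {
    a <- values[group == pairs[1L, k]]
    b <- values[group == pairs[2L, k]]
    p <- if (stats::sd(c(a, b)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    ph$p_raw[k] <- p
    ph$p_bonferroni[k] <- min(1, p * n_pairs)
  }
  list(H = unname(kw$statistic), p = kw$p.value, post_hoc = ph,
       test = "kruskal-wallis")
}

#' Statistical table over several scalar metrics
#'
#' Applies the normality gate and [kruskal_wallis_with_posthoc()] to each
#' column; the layout mirrors a metric x (H, p) report.
#'
#' @param values Subjects x metrics matrix.
#' @param group Factor of group labels.
#' @return Data frame: metric, H, p, plus one Bonferroni post hoc column per
#'   group pair.
#' @export
metric_group_table <- function(values, group) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("metric", seq_len(ncol(values)))
  lv <- levels(factor(group))
  pair_names <- paste0("p_", apply(utils::combn(lv, 2L), 2L, paste,
                                   collapse = "/"))
  rows <- lapply(seq_len(ncol(values)), function(j) {
    r <- kruskal_wallis_with_posthoc(values[, j], group)
    ph <- stats::setNames(rep(NA_real_, length(pair_names)), pair_names)
    if (!is.null(r$post_hoc))
      ph[paste0("p_", r$post_hoc$pair)] <- r$post_hoc$p_bonferroni
    cbind(data.frame(metric = colnames(values)[j], H = r$H, p = r$p),
          as.data.frame(as.list(ph), check.names = FALSE))
  })
  do.call(rbind, rows)
}

#' Edge-wise one-way ANOVA with Bonferroni correction over edges
#'
#' A vectorized F-test per edge feature across groups;
#' `p_corrected = min(1, p_raw * n_edges)` (the per-band edge family), and a
#' significance mask at `alpha` on the corrected p. Edges with zero
#' within-group variance but distinct group means receive infinite F and are
#' reported significant with `degenerate = TRUE`.
#'
#' @param values Subjects x edges matrix.
#' @param group Factor of group labels.
#' @param alpha Family-wise level on corrected p-values, default 0.05.
#' @return Data frame per edge: `F`, `p_raw`, `p_corrected`, `significant`,
#'   `degenerate`.
#' @export
anova_edgewise <- function(values, group, alpha = 0.05) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  group <- factor(group)
  stopifnot(nrow(values) == length(group), nlevels(group) >= 2L)
  n <- nrow(values)
  k <- nlevels(group)
  gm <- rowsum(values, group) / as.vector(table(group))   # k x edges means
  grand <- colMeans(values)
  ng <- as.vector(table(group))
  ssb <- colSums(ng * (gm - matrix(grand, k, ncol(values), byrow = TRUE))^2)
  ssw <- colSums((values - gm[as.integer(group), , drop = FALSE])^2)
  df1 <- k - 1L
  df2 <- n - k
  Fstat <- (ssb / df1) / (ssw / df2)
  degenerate <- ssw == 0 & ssb > 0
  Fstat[degenerate] <- Inf
  p_raw <- ifelse(is.infinite(Fstat), 0, stats::pf(Fstat, df1, df2,
                                                   lower.tail = FALSE))
  p_raw[ssw == 0 & ssb == 0] <- 1
  p_corr <- pmin(1, p_raw * ncol(values))
  data.frame(F = Fstat, p_raw = p_raw, p_corrected = p_corr,
             significant = p_corr < alpha, degenerate = degenerate,
             row.names = colnames(values))
}

#' Desikan-Killiany 68-ROI table with 7-region lobe grouping
#'
#' The 34 cortical parcels per hemisphere of the DK atlas, each assigned to
#' one of seven reporting regions: frontal, temporal, parietal, occipital,
#' posterior cingulate (PCC), anterior cingulate (ACC), insula. Left
#' hemisphere ROIs come first (indices 1-34), then right (35-68).
#'
#' @return Data frame with columns `roi` (index), `name`, `hemisphere`,
#'   `region`.
#' @export
dk_roi_table <- function() {
  region_of <- c(
    bankssts = "temporal", caudalanteriorcingulate = "ACC",
    caudalmiddlefrontal = "frontal", cuneus = "occipital",
    entorhinal = "temporal", fusiform = "temporal",
    inferiorparietal = "parietal", inferiortemporal = "temporal",
    isthmuscingulate = "PCC", lateraloccipital = "occipital",
    lateralorbitofrontal = "frontal", lingual = "occipital",
    medialorbitofrontal = "frontal", middletemporal = "temporal",
    parahippocampal = "temporal", paracentral = "frontal",
    parsopercularis = "frontal", parsorbitalis = "frontal",
    parstriangularis = "frontal", pericalcarine = "occipital",
    postcentral = "parietal", posteriorcingulate = "PCC",
    precentral = "frontal", precuneus = "parietal",
    rostralanteriorcingulate = "ACC", rostralmiddlefrontal = "frontal",
    superiorfrontal = "frontal", superiorparietal = "parietal",
    superiortemporal = "temporal", supramarginal = "parietal",
    frontalpole = "frontal", temporalpole = "temporal",
    transversetemporal = "temporal", insula = "insula")
  parcels <- names(region_of)
  data.frame(
    roi = seq_len(68L),
    name = c(paste0("lh_", parcels), paste0("rh_", parcels)),
    hemisphere = rep(c("lh", "rh"), each = 34L),
    region = rep(unname(region_of), 2L),
    stringsAsFactors = FALSE)
}

#' Count significant edges per 7-region pair
#'
#' Folds an edge-level significance mask (over the row-major upper triangle
#' of an `n_rois` x `n_rois` matrix) into a symmetric 7 x 7 count matrix of
#' the lobe-level reporting regions.
#'
#' @param edge_mask Logical vector over edges (length
#'   `n_rois (n_rois - 1) / 2`, row-major upper triangle).
#' @param roi_region Character vector, ROI index -> region name (default the
#'   [dk_roi_table()] grouping for 68 ROIs).
#' @return Symmetric region x region integer count matrix; the total over
#'   the upper triangle plus diagonal equals `sum(edge_mask)`.
#' @export
roi_group_summary <- function(edge_mask, roi_region = dk_roi_table()$region) {
  n_roi <- length(roi_region)
  idx <- upper_tri_index(n_roi)
  if (length(edge_mask) != nrow(idx))
    stop("edge mask length does not match the ROI count")
  if (anyNA(roi_region)) stop("every ROI must be mapped to a region")
  regions <- unique(roi_region)
  M <- matrix(0L, length(regions), length(regions),
              dimnames = list(regions, regions))
  sig <- which(edge_mask)
  for (e in sig) {
    a <- roi_region[idx[e, 1L]]
    b <- roi_region[idx[e, 2L]]
    M[a, b] <- M[a, b] + 1L
    if (a != b) M[b, a] <- M[b, a] + 1L
  }
  M
}
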