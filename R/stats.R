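# Group-difference statistics: Kruskal-Wallis omnibus, Dunn post-hoc with
# Benjamini-Hochberg FDR, and site x band significance matrices.

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H with tie correction, p from chi-square with k - 1 df.
#' Identical values across all groups give H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length, k >= 2 levels.
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (length(values) < 3L) stop("need total N >= 3", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(H = 0, p = 1, df = nlevels(groups) - 1L))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Dunn's rank-based pairwise post-hoc tests with BH-FDR correction
#'
#' All group pairs are compared by Dunn's z statistic on the joint ranks
#' (with tie correction); p-values are adjusted across the pairwise family
#' by the Benjamini-Hochberg step-up procedure.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param alpha significance level applied to the adjusted q-values (0.05).
#' @return Data frame: `group1`, `group2`, `z`, `p`, `q`, `significant`.
#' @export
posthoc_fdr <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- combn(levels(groups), 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ng[[a]] + 1 / ng[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    res$z[i] <- z
    res$p[i] <- 2 * pnorm(-abs(z))
  }
  res$q <- p.adjust(res$p, method = "BH")
  res$significant <- res$q < alpha
  res
}

#' Full group statistics over a tidy reconfiguration table
#'
#' Runs the omnibus per metric x band x site and, where requested, Dunn
#' post-hoc pairwise tests with BH-FDR applied within each metric x band
#' family (matching per-figure correction).
#'
#' @param table tidy data frame with columns `subject_id`, `group`, `band`,
#'   `site`, `metric`, `value` (site `"global"` holds community-level
#'   metrics).
#' @param alpha significance level.
#' @return List with `omnibus` (metric, band, site, H, p) and `pairwise`
#'   (metric, band, site, group1, group2, z, p, q, significant).
#' @export
group_stats <- function(table, alpha = 0.05) {
  need <- c("subject_id", "group", "band", "site", "metric", "value")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  omni <- NULL
  pair <- NULL
  for (m in unique(table$metric)) {
    for (b in unique(table$band)) {
      sub_mb <- table[table$metric == m & table$band == b, ]
      pw_mb <- NULL
      for (s in unique(sub_mb$site)) {
        d <- sub_mb[sub_mb$site == s, ]
        d <- d[is.finite(d$value), ]
        if (length(unique(d$group)) < 2L || nrow(d) < 3L) next
        kw <- kruskal_wallis(d$value, d$group)
        omni <- rbind(omni, data.frame(metric = m, band = b, site = s,
                                       H = kw$H, p = kw$p,
                                       stringsAsFactors = FALSE))
        ph <- posthoc_fdr(d$value, d$group, alpha)
        ph$metric <- m; ph$band <- b; ph$site <- s
        pw_mb <- rbind(pw_mb, ph)
      }
      if (!is.null(pw_mb)) {
        # FDR family: all pairs and sites within this metric x band
        pw_mb$q <- p.adjust(pw_mb$p, method = "BH")
        pw_mb$significant <- pw_mb$q < alpha
        pair <- rbind(pair, pw_mb)
      }
    }
  }
  list(omnibus = omni, pairwise = pair)
}

#' Site x band significance matrix for one group pair
#'
#' 0/1 matrix (rows = sites, columns = bands) marking FDR-significant
#' differences for `metric` between two groups, mirroring the pairwise
#' heatmap layout.
#'
#' @param stats result of [group_stats()].
#' @param metric metric name.
#' @param group1,group2 group pair (order-insensitive).
#' @param sites,bands row/column orders (defaults: orders of appearance).
#' @return Integer matrix of 0/1.
#' @export
significance_matrix <- function(stats, metric, group1, group2,
                                sites = NULL, bands = NULL) {
  pw <- stats$pairwise
  pw <- pw[pw$metric == metric &
             ((pw$group1 == group1 & pw$group2 == group2) |
                (pw$group1 == group2 & pw$group2 == group1)), ]
  if (is.null(sites)) sites <- unique(pw$site)
  if (is.null(bands)) bands <- unique(pw$band)
  m <- matrix(0L, length(sites), length(bands),
              dimnames = list(sites, bands))
  for (i in seq_len(nrow(pw)))
    if (pw$site[i] %in% sites && pw$band[i] %in% bands)
      m[pw$site[i], pw$band[i]] <- as.integer(pw$significant[i])
  m
}

#' Plot a significance matrix
#'
#' Plain image of a 0/1 site x band matrix (bright = significant).
#'
#' @param m matrix from [significance_matrix()].
#' @param main plot title.
#' @return Invisibly, `m`.
#' @export
plot_significance_matrix <- function(m, main = "") {
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                  col = grDevices::hcl.colors(2, "Blue-Yellow"),
                  axes = FALSE, xlab = "band", ylab = "", main = main)
  graphics::axis(1, seq_len(ncol(m)), colnames(m))
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2)
  invisible(m)
}
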