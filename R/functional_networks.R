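#' Between-cluster correlation matrix of condition firing
#'
#' Pearson correlation between cluster mean condition-bin profiles
#' (cluster means recomputed from `x` so they match the feature space).
#' A zero-variance cluster profile yields `NA` correlations for its pairs.
#'
#' @param clusters a `cluster_model`.
#' @param x the `profile_matrix` the clusters were fit on.
#' @return symmetric `k x k` correlation matrix with unit diagonal.
#' @export
cluster_correlation_matrix <- function(clusters, x) {
  if (clusters$k < 2) fail("need >= 2 clusters")
  asg <- clusters$assignments[rownames(x)]
  cent <- do.call(rbind, lapply(seq_len(clusters$k), function(cl) {
    colMeans(x[asg == cl, , drop = FALSE])
  }))
  rownames(cent) <- paste0("k", seq_len(clusters$k))
  keep_sd <- apply(cent, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(cent)))
  cc[keep_sd == 0, ] <- NA_real_
  cc[, keep_sd == 0] <- NA_real_
  diag(cc) <- 1
  cc
}

#' Detect correlated cluster networks
#'
#' Groups clusters by average-linkage hierarchical clustering on the
#' correlation distance `1 - r`, cut so that the mean between-group
#' correlation at each surviving merge is at least `threshold`. Groups of
#' two or more clusters whose mean pairwise correlation clears the
#' threshold become networks (labeled `net1`, `net2`, ... in decreasing
#' size); all remaining clusters are labeled `"none"`. In the cue-period
#' analysis the (single) detected network is the cue subnetwork and the
#' `"none"` clusters form the supranetwork.
#'
#' @param corr correlation matrix from [cluster_correlation_matrix()].
#' @param threshold minimum mean within-group correlation (default 0.5).
#' @return named character vector: network label per cluster, with
#'   attribute `threshold`.
#' @export
detect_networks <- function(corr, threshold = 0.5) {
  k <- nrow(corr)
  labels <- rownames(corr)
  if (is.null(labels)) labels <- paste0("k", seq_len(k))
  part <- stats::setNames(rep("none", k), labels)
  if (k >= 2) {
    cc <- corr
    cc[is.na(cc)] <- -1 # undefined pairs can never bind a network
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    grp <- stats::cutree(hc, h = 1 - threshold)
    for (g in unique(grp)) {
      members <- which(grp == g)
      while (length(members) >= 2) {
        sub <- cc[members, members, drop = FALSE]
        mean_r <- (sum(sub) - length(members)) /
          (length(members)^2 - length(members))
        if (mean_r >= threshold) break
        # drop the most weakly coupled member and re-check
        coupling <- rowMeans(sub) - 1 / length(members)
        members <- members[-which.min(coupling)]
      }
      if (length(members) >= 2) part[members] <- paste0("grp", g)
    }
    nets <- setdiff(unique(part), "none")
    if (length(nets)) {
      sizes <- vapply(nets, function(nm) sum(part == nm), numeric(1))
      relabel <- stats::setNames(paste0("net", seq_along(nets)),
                                 nets[order(-sizes)])
      part[part != "none"] <- relabel[part[part != "none"]]
    }
  }
  attr(part, "threshold") <- threshold
  part
}

#' Hub scores of network neurons
#'
#' For every neuron belonging to a cluster of the target network, the
#' Pearson correlation between its own condition profile and the mean
#' profile of each fellow network cluster (its own cluster excluded),
#' averaged over fellow clusters. High-scoring clusters are hub candidates.
#' A network with fewer than 2 clusters admits no fellow-cluster
#' correlation; the analysis is skipped with a message and `NULL` returned.
#'
#' @param x the `profile_matrix`.
#' @param clusters the `cluster_model`.
#' @param partition network labels from [detect_networks()].
#' @param network target network label (default `"net1"`).
#' @return list with `units` (data.frame `neuron_id`, `cluster`,
#'   `hub_score`) and `cluster_means` (data.frame `cluster`,
#'   `mean_hub_score`), or `NULL` when the network has < 2 clusters.
#' @export
hub_scores <- function(x, clusters, partition, network = "net1") {
  net_cl <- which(partition == network)
  if (length(net_cl) < 2) {
    message("hub analysis skipped: network '", network,
            "' has fewer than 2 clusters")
    return(NULL)
  }
  asg <- clusters$assignments[rownames(x)]
  cent <- do.call(rbind, lapply(net_cl, function(cl) {
    colMeans(x[asg == cl, , drop = FALSE])
  }))
  in_net <- which(asg %in% net_cl)
  units <- do.call(rbind, lapply(in_net, function(i) {
    own <- asg[i]
    fellows <- which(net_cl != own)
    rs <- vapply(fellows, function(j) {
      suppressWarnings(stats::cor(x[i, ], cent[j, ]))
    }, numeric(1))
    data.frame(neuron_id = rownames(x)[i], cluster = unname(own),
               hub_score = mean(rs, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  cluster_means <- do.call(rbind, lapply(net_cl, function(cl) {
    data.frame(cluster = cl,
               mean_hub_score = mean(units$hub_score[units$cluster == cl]))
  }))
  list(units = units, cluster_means = cluster_means)
}

# classical Levene test (mean-centered): one-way ANOVA on |x - group mean|
.levene_test <- function(values, groups) {
  groups <- factor(groups)
  centers <- stats::ave(values, groups, FUN = mean)
  dev <- abs(values - centers)
  tab <- summary(stats::aov(dev ~ groups))[[1]]
  list(statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1])
}

#' Regional composition of functional networks
#'
#' Proportion of each network's neurons found in each region, plus, for a
#' chosen pair of networks, per-region two-tailed independent-samples
#' t-tests and Levene tests on the in-region membership indicator,
#' Bonferroni-corrected over the number of regions tested.
#'
#' @param regions character vector of region labels, one per neuron.
#' @param networks character vector of network labels, one per neuron.
#' @param compare length-2 character: which two networks to contrast;
#'   defaults to the two largest groups.
#' @return list with `composition` (data.frame `region`, one proportion
#'   column per network, each column summing to 1) and `tests` (data.frame
#'   per region: `t_statistic`, `t_p`, `t_p_bonf`, `levene_f`, `levene_p`,
#'   `levene_p_bonf`).
#' @export
regional_composition <- function(regions, networks, compare = NULL) {
  stopifnot(length(regions) == length(networks))
  keep <- !is.na(regions) & !is.na(networks)
  regions <- regions[keep]
  networks <- networks[keep]
  regs <- sort(unique(regions))
  nets <- names(sort(table(networks), decreasing = TRUE))
  composition <- data.frame(region = regs)
  for (nm in nets) {
    r <- regions[networks == nm]
    composition[[nm]] <- as.numeric(table(factor(r, levels = regs))) /
      length(r)
  }
  if (is.null(compare)) compare <- head(nets, 2)
  tests <- NULL
  if (length(compare) == 2 && all(compare %in% nets)) {
    a <- regions[networks == compare[1]]
    b <- regions[networks == compare[2]]
    tests <- do.call(rbind, lapply(regs, function(rg) {
      xa <- as.numeric(a == rg)
      xb <- as.numeric(b == rg)
      tt <- tryCatch(
        stats::t.test(xa, xb, var.equal = TRUE),
        error = function(e) list(statistic = NA_real_, p.value = NA_real_))
      lv <- tryCatch(
        .levene_test(c(xa, xb), rep(compare, c(length(xa), length(xb)))),
        error = function(e) list(statistic = NA_real_, p_value = NA_real_))
      data.frame(region = rg,
                 t_statistic = unname(tt$statistic), t_p = tt$p.value,
                 levene_f = lv$statistic, levene_p = lv$p_value,
                 stringsAsFactors = FALSE)
    }))
    tests$t_p_bonf <- stats::p.adjust(tests$t_p, "bonferroni")
    tests$levene_p_bonf <- stats::p.adjust(tests$levene_p, "bonferroni")
  }
  list(composition = composition, tests = tests, compare = compare)
}

#' Chi-squared test of network membership proportion
#'
#' One-sample goodness-of-fit test of an observed in-network count against
#' an expected proportion `p0`: `chi^2 = sum (obs - exp)^2 / exp` over the
#' in/out cells, df = 1, no continuity correction. Used to ask whether the
#' fraction of outcome-network neurons that also belong to the cue
#' subnetwork differs from the subnetwork's overall share.
#'
#' @param observed_in neurons of the group inside the reference network.
#' @param total group size.
#' @param p0 expected proportion (0 < p0 < 1).
#' @return a `membership_stats` list: `observed_in`, `total`, `proportion`,
#'   `p0`, `chi_square`, `df`, `p_value`.
#' @export
#' @examples
#' membership_chi_square(85, 265, 505 / 1812)
membership_chi_square <- function(observed_in, total, p0) {
  if (total <= 0) fail("total must be positive")
  if (observed_in < 0 || observed_in > total) {
    fail("observed_in must lie in [0, total]")
  }
  if (p0 <= 0 || p0 >= 1) fail("p0 must lie strictly in (0, 1)")
  obs <- c(observed_in, total - observed_in)
  expd <- c(total * p0, total * (1 - p0))
  chi <- sum((obs - expd)^2 / expd)
  structure(list(observed_in = observed_in, total = total,
                 proportion = observed_in / total, p0 = p0,
                 chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE)),
            class = "membership_stats")
}

#' @export
print.membership_stats <- function(x, ...) {
  cat(sprintf("membership: %d/%d (%.1f%%) vs expected %.1f%%; chi2(1) = %.3f, p = %.3g\n",
              x$observed_in, x$total, 100 * x$proportion, 100 * x$p0,
              x$chi_square, x$p_value))
  invisible(x)
}
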