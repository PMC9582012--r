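#' Cue-period design matrix: threat probability vs fear behavior
#'
#' Per-trial regressors for the cue-period encoding regression: `P`, the
#' cue's shock probability (1.00 danger / 0.25 uncertainty / 0.00 safety),
#' and `SR`, the trial's observed suppression ratio. Trials with an
#' undefined suppression ratio are dropped. Both regressors are
#' z-standardized across the retained trials by default (raw coding
#' available), so that firing tracking threat probability — invariant of
#' suppression — and firing tracking behavior — invariant of probability —
#' load on comparable scales.
#'
#' @param trials trial table (with `p`).
#' @param behavior output of [behavior_records()].
#' @param standardize z-score the regressors (default `TRUE`).
#' @return a `design_matrix` data.frame: `trial_id`, `P`, `SR`; attributes
#'   `regressors`, `standardized`, `mode = "cue"`.
#' @export
build_cue_design <- function(trials, behavior, standardize = TRUE) {
  sr <- behavior$suppression_ratio[match(trials$trial_id, behavior$trial_id)]
  keep <- !is.na(sr)
  if (!any(keep)) fail("all trials have missing suppression ratios")
  d <- data.frame(trial_id = trials$trial_id[keep],
                  P = trials$p[keep], SR = sr[keep])
  .finish_design(d, c("P", "SR"), standardize, mode = "cue")
}

#' Outcome-period design matrix: sensory shock vs prediction error
#'
#' Per-trial regressors for the outcome-period regression: `SHOCK`, an
#' indicator equating shock delivery on danger and uncertainty trials, and
#' `PE`, the aversive prediction error. Under the default residual coding
#' `PE = outcome - P` (danger-shock 0, uncertainty-shock +0.75,
#' uncertainty-omission -0.25, safety 0); the alternative indicator coding
#' marks surprising shock (uncertainty-shock trials) only.
#'
#' @param trials trial table.
#' @param pe_coding `"residual"` (outcome - P) or `"indicator"`.
#' @param standardize z-score the regressors (default `FALSE`, keeping
#'   betas in firing units per unit regressor).
#' @return a `design_matrix` data.frame: `trial_id`, `SHOCK`, `PE`;
#'   attributes `regressors`, `standardized`, `mode = "outcome"`.
#' @export
build_outcome_design <- function(trials,
                                 pe_coding = c("residual", "indicator"),
                                 standardize = FALSE) {
  pe_coding <- match.arg(pe_coding)
  pe <- if (pe_coding == "residual") {
    trials$outcome - trials$p
  } else {
    as.numeric(trials$cue == "uncertainty" & trials$shock_delivered)
  }
  d <- data.frame(trial_id = trials$trial_id,
                  SHOCK = trials$outcome, PE = pe)
  .finish_design(d, c("SHOCK", "PE"), standardize, mode = "outcome")
}

.finish_design <- function(d, regressors, standardize, mode) {
  for (rg in regressors) {
    if (stats::sd(d[[rg]]) == 0) {
      fail("regressor ", rg, " is constant over the retained trials")
    }
    if (standardize) d[[rg]] <- as.numeric(scale(d[[rg]]))
  }
  structure(d, regressors = regressors, standardized = standardize,
            mode = mode, class = c("design_matrix", "data.frame"))
}

#' Per-unit, per-bin encoding regression
#'
#' For every neuron and time bin, ordinary least squares of binned firing
#' rate on an intercept plus both regressors simultaneously (so each beta
#' is the signal unique to its regressor given the other). Returns betas
#' and standard errors.
#'
#' @param tensor a `firing_tensor` (raw counts or normalized; rates are
#'   fit as counts / bin width when unnormalized).
#' @param design a `design_matrix`; the tensor is subset to its trials.
#' @return an `encoding_fit`: list with `beta` and `se` arrays
#'   (`neurons x bins x regressors`), `regressors`, `time`, `n_trials`.
#' @export
fit_unit_encoding <- function(tensor, design) {
  regs <- attr(design, "regressors")
  tix <- match(as.character(design$trial_id), dimnames(tensor)[[2]])
  if (anyNA(tix)) fail("design refers to trials absent from the tensor")
  X <- cbind(intercept = 1, as.matrix(design[, regs, drop = FALSE]))
  if (nrow(X) < ncol(X) + 2) fail("need >= ", ncol(X) + 2, " usable trials")
  qx <- qr(X)
  if (qx$rank < ncol(X)) fail("design matrix is rank deficient")
  xtxi <- chol2inv(qr.R(qx))
  hat <- xtxi %*% t(X)
  scale_f <- if (attr(tensor, "normalization") == "none") {
    1 / attr(tensor, "bin_width_s")
  } else 1
  n_neu <- dim(tensor)[1]
  n_bin <- dim(tensor)[3]
  beta <- array(NA_real_, c(n_neu, n_bin, length(regs)),
                dimnames = list(dimnames(tensor)[[1]], dimnames(tensor)[[3]],
                                regs))
  se <- beta
  dfree <- nrow(X) - ncol(X)
  for (i in seq_len(n_neu)) {
    y <- tensor[i, tix, , drop = FALSE] # trials x bins
    dim(y) <- c(length(tix), n_bin)
    y <- y * scale_f
    b <- hat %*% y                      # p x bins
    res <- y - X %*% b
    sigma2 <- colSums(res^2) / dfree
    se_b <- sqrt(outer(diag(xtxi), sigma2)) # p x bins
    beta[i, , ] <- t(b[-1, , drop = FALSE])
    se[i, , ] <- t(se_b[-1, , drop = FALSE])
  }
  structure(list(beta = beta, se = se, regressors = regs,
                 time = attr(tensor, "time"), n_trials = nrow(X)),
            class = "encoding_fit")
}

#' Cluster-mean beta profiles
#'
#' Averages the per-unit betas over the neurons of each cluster, giving one
#' signaling time course per cluster and regressor.
#'
#' @param fit an `encoding_fit`.
#' @param clusters a `cluster_model` covering the fitted neurons.
#' @return a `beta_profile`: array `clusters x bins x regressors` with
#'   attributes `time` and `regressors`.
#' @export
cluster_beta_profiles <- function(fit, clusters) {
  ids <- dimnames(fit$beta)[[1]]
  asg <- clusters$assignments[ids]
  if (anyNA(asg)) fail("clusters must cover all fitted neurons")
  out <- array(NA_real_, c(clusters$k, dim(fit$beta)[2], dim(fit$beta)[3]),
               dimnames = list(paste0("k", seq_len(clusters$k)),
                               dimnames(fit$beta)[[2]], fit$regressors))
  for (cl in seq_len(clusters$k)) {
    members <- which(asg == cl)
    if (!length(members)) fail("cluster ", cl, " is empty")
    sl <- fit$beta[members, , , drop = FALSE]
    out[cl, , ] <- apply(sl, c(2, 3), mean)
  }
  structure(out, time = fit$time, regressors = fit$regressors,
            class = c("beta_profile", "array"))
}

# regressor-major flattening: all bins of regressor 1, then regressor 2
.flatten_beta_profile <- function(profile) {
  regs <- attr(profile, "regressors")
  k <- dim(profile)[1]
  nb <- dim(profile)[2]
  flat <- do.call(cbind, lapply(seq_along(regs), function(r) {
    m <- profile[, , r, drop = TRUE]
    dim(m) <- c(k, nb)
    colnames(m) <- paste0(regs[r], ".", dimnames(profile)[[2]])
    m
  }))
  rownames(flat) <- dimnames(profile)[[1]]
  flat
}

#' PCA of cluster signaling (beta) time courses
#'
#' PCA with clusters as observations and the concatenated
#' regressor-by-bin beta weights as features (mean-centered). Loadings are
#' returned both flat and reshaped into per-regressor time courses. PC1's
#' sign is fixed so its mean loading over the `orient` regressor's bins is
#' positive (fear-behavior betas in cue mode, shock betas in outcome mode).
#'
#' @param profile a `beta_profile`.
#' @param orient regressor name fixing PC1's sign; defaults to `"SR"` when
#'   present, else `"SHOCK"`, else the first regressor.
#' @return a `signaling_pca`: list with `var_explained` (% signaling
#'   variance per PC), `pc_variance` (absolute variance per PC),
#'   `loadings` (features x PCs), `loading_curves` (array
#'   `regressors x bins x PCs`), `scores`, `time`, `regressors`.
#' @export
signaling_pca <- function(profile, orient = NULL) {
  regs <- attr(profile, "regressors")
  k <- dim(profile)[1]
  if (k < 2) fail("need >= 2 clusters")
  nb <- dim(profile)[2]
  flat <- .flatten_beta_profile(profile)
  if (all(apply(flat, 2, stats::sd) == 0)) fail("degenerate beta profiles")
  p <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  if (is.null(orient)) {
    orient <- if ("SR" %in% regs) "SR" else if ("SHOCK" %in% regs) "SHOCK" else regs[1]
  }
  oc <- rep(regs, each = nb) == orient
  if (mean(p$rotation[oc, 1]) < 0) {
    p$rotation[, 1] <- -p$rotation[, 1]
    p$x[, 1] <- -p$x[, 1]
  }
  npc <- ncol(p$rotation)
  curves <- array(NA_real_, c(length(regs), nb, npc),
                  dimnames = list(regs, dimnames(profile)[[2]],
                                  colnames(p$rotation)))
  for (r in seq_along(regs)) {
    curves[r, , ] <- p$rotation[rep(regs, each = nb) == regs[r], ,
                                drop = FALSE]
  }
  structure(list(var_explained = ve, pc_variance = p$sdev^2,
                 loadings = p$rotation, loading_curves = curves,
                 scores = p$x, time = attr(profile, "time"),
                 regressors = regs),
            class = "signaling_pca")
}

#' @export
print.signaling_pca <- function(x, ...) {
  cat("Signaling PCA over", nrow(x$scores), "clusters; PC1 =",
      sprintf("%.1f%%,", x$var_explained[1]), "PC2 =",
      sprintf("%.1f%%", ifelse(length(x$var_explained) > 1,
                               x$var_explained[2], NA)),
      "of signaling variance\n")
  invisible(x)
}

#' In-silico network lesion of signaling PCA
#'
#' "Lesions" one functional network by shuffling the trial labels of every
#' neuron in its clusters (independent per-neuron permutation of trials,
#' destroying trial-linked structure while preserving each neuron's
#' marginal firing), then refits the per-unit encoding regressions,
#' rebuilds cluster beta profiles and reruns the signaling PCA. Repeating
#' over shuffles yields the mean lesioned % variance per PC and its change
#' from the intact analysis; per-PC lesioned loading curves are averaged
#' after sign-aligning each shuffle's PCs to the intact ones.
#'
#' Because re-run PCs renormalize to the (reduced) lesioned total variance
#' and can reorder, the result also reports `axis_variance`: the variance
#' of the lesioned beta profiles along each *intact* PC axis. A signal
#' carried by the lesioned network shows a large drop of its axis
#' variance; a signal carried elsewhere persists.
#'
#' @param tensor the `firing_tensor` used for the intact fit.
#' @param clusters the `cluster_model`.
#' @param partition network labels per cluster from [detect_networks()].
#' @param target network label to lesion.
#' @param design the `design_matrix`.
#' @param n_shuffles number of lesion shuffles (default 100).
#' @param seed integer seed.
#' @param n_pc number of PCs summarized (default 2).
#' @return a `lesion_result`: list with `target`, `intact`
#'   (`signaling_pca`), `lesioned_ve_mean`, `lesioned_ve_sd`, `delta_ve`
#'   (lesioned - intact, percentage points), `axis_variance` (data.frame
#'   per intact PC: intact variance, lesioned mean/sd along that axis),
#'   `lesioned_curves` (mean loading curves), `n_shuffles`, `seed`.
#' @export
lesion_network_signaling <- function(tensor, clusters, partition, target,
                                     design, n_shuffles = 100, seed = 1L,
                                     n_pc = 2) {
  if (n_shuffles < 1) fail("n_shuffles must be >= 1")
  net_cl <- which(partition == target)
  if (!length(net_cl)) fail("target network '", target, "' is empty")
  intact_fit <- fit_unit_encoding(tensor, design)
  intact <- signaling_pca(cluster_beta_profiles(intact_fit, clusters))
  asg <- clusters$assignments[dimnames(tensor)[[1]]]
  lesion_ids <- which(asg %in% net_cl)
  tix <- match(as.character(design$trial_id), dimnames(tensor)[[2]])
  n_pc <- min(n_pc, length(intact$var_explained))
  axes <- intact$loadings[, seq_len(n_pc), drop = FALSE]
  ve_mat <- matrix(NA_real_, n_shuffles, n_pc)
  ax_mat <- matrix(NA_real_, n_shuffles, n_pc)
  curve_sum <- array(0, dim = c(dim(intact$loading_curves)[1:2], n_pc))
  set.seed(derive_seed(seed, "lesion", target))
  for (s in seq_len(n_shuffles)) {
    tens_s <- tensor
    for (i in lesion_ids) {
      perm <- sample(tix)
      tens_s[i, tix, ] <- tensor[i, perm, ]
    }
    fit_s <- fit_unit_encoding(tens_s, design)
    prof_s <- cluster_beta_profiles(fit_s, clusters)
    pca_s <- signaling_pca(prof_s)
    ve_mat[s, ] <- pca_s$var_explained[seq_len(n_pc)]
    flat_s <- .flatten_beta_profile(prof_s)
    proj <- sweep(flat_s, 2, colMeans(flat_s)) %*% axes
    ax_mat[s, ] <- apply(proj, 2, function(v) sum(v^2) / (length(v) - 1))
    for (pc in seq_len(n_pc)) {
      a <- as.vector(pca_s$loadings[, pc])
      b <- as.vector(intact$loadings[, pc])
      sgn <- if (sum(a * b) < 0) -1 else 1
      curve_sum[, , pc] <- curve_sum[, , pc] +
        sgn * pca_s$loading_curves[, , pc]
    }
  }
  curves <- curve_sum / n_shuffles
  dimnames(curves) <- c(dimnames(intact$loading_curves)[1:2],
                        list(colnames(intact$loadings)[seq_len(n_pc)]))
  axis_variance <- data.frame(
    pc = seq_len(n_pc),
    intact = intact$pc_variance[seq_len(n_pc)],
    lesioned_mean = colMeans(ax_mat),
    lesioned_sd = apply(ax_mat, 2, stats::sd))
  structure(list(target = target, intact = intact,
                 lesioned_ve_mean = colMeans(ve_mat),
                 lesioned_ve_sd = apply(ve_mat, 2, stats::sd),
                 delta_ve = colMeans(ve_mat) -
                   intact$var_explained[seq_len(n_pc)],
                 axis_variance = axis_variance,
                 lesioned_curves = curves,
                 n_shuffles = n_shuffles, seed = seed),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat("Lesion of network '", x$target, "' (", x$n_shuffles, " shuffles)\n",
      sep = "")
  for (pc in seq_along(x$lesioned_ve_mean)) {
    cat(sprintf("  PC%d: intact %.1f%% -> lesioned %.1f%% (delta %+.1f)\n",
                pc, x$intact$var_explained[pc], x$lesioned_ve_mean[pc],
                x$delta_ve[pc]))
  }
  invisible(x)
}
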