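#' Configure a feature selector
#'
#' One configuration object drives all three selection routes:
#'
#' * `rf` / `svm` — stability selection: the model is refitted on
#'   `external_iterations` stratified subsamples of `subsample_fraction` of
#'   the genomes; within each refit a per-iteration rule picks families
#'   (Gini importance above the iteration mean for `rf`; |weight| z-score
#'   above `svm_zscore` for `svm`), a permutation gate discards iterations
#'   indistinguishable from label noise, and families picked in at least
#'   `appearance_threshold` of the iterations are retained.
#' * `lr` — a single L2-penalised logistic regression (LBFGS solver capped at
#'   `lr_max_iterations` internal iterations); each family's contribution
#'   share is |coefficient| / sum of |coefficients|, and retention follows
#'   `lr_contribution_mode` (see [lr_contribution_retain()]).
#'
#' @param method one of `"lr"`, `"svm"`, `"rf"`.
#' @param external_iterations number of stability refits for rf/svm
#'   (default 100).
#' @param appearance_threshold minimum fraction of iterations in which a
#'   family must be selected to be retained (default 0.40, inclusive).
#' @param subsample_fraction fraction of genomes per stratified subsample
#'   (default 0.9).
#' @param rf_num_trees trees per random-forest refit (default 100; Gini
#'   impurity).
#' @param svm_alpha L2 penalty of the SGD-trained linear SVM (default 1e-2).
#' @param svm_epochs SGD passes over the subsample per refit (default 80).
#' @param svm_zscore per-iteration |weight| z-score cutoff (default 3.0).
#' @param null_gate_permutations label-permuted refits per iteration used to
#'   gate the per-iteration selection (default 3; 0 disables the gate). A
#'   fixed random labeling of a wide matrix carries persistent chance
#'   associations, so without a per-iteration signal check stability
#'   selection would retain them; the gate compares each refit's signal
#'   strength (maximum Gini importance for rf; inverse mean |weight| for
#'   svm, since a hinge fit to label noise needs much larger weights for the
#'   same margin) against the strongest of the permuted refits, and an
#'   iteration whose strength does not exceed `null_gate_factor` times that
#'   reference selects nothing.
#' @param null_gate_factor signal-to-permuted strength ratio an iteration
#'   must exceed (default 2.0).
#' @param lr_max_iterations LBFGS internal-iteration cap (default 300).
#' @param lr_contribution_threshold contribution cutoff as a fraction of the
#'   total coefficient mass (default 0.003, i.e. 0.3%).
#' @param lr_contribution_mode `"individual_share"` (default) retains every
#'   family whose own share exceeds the threshold; `"cumulative_prefix"`
#'   retains the shortest run of top-ranked families whose summed share
#'   exceeds it.
#' @param seed integer seed; all subsampling and fitting randomness derives
#'   from it.
#' @return An object of class `selector_config`.
#' @export
selector_config <- function(method = c("lr", "svm", "rf"),
                            external_iterations = 100L,
                            appearance_threshold = 0.40,
                            subsample_fraction = 0.9,
                            rf_num_trees = 100L,
                            svm_alpha = 1e-2,
                            svm_epochs = 80L,
                            svm_zscore = 3.0,
                            null_gate_permutations = 3L,
                            null_gate_factor = 2.0,
                            lr_max_iterations = 300L,
                            lr_contribution_threshold = 0.003,
                            lr_contribution_mode = c("individual_share",
                                                     "cumulative_prefix"),
                            seed = 1L) {
  structure(list(
    method = match.arg(method),
    external_iterations = check_count(external_iterations,
                                      "external_iterations", min = 1L),
    appearance_threshold = check_fraction(appearance_threshold,
                                          "appearance_threshold",
                                          allow_zero = FALSE),
    subsample_fraction = check_fraction(subsample_fraction,
                                        "subsample_fraction",
                                        allow_zero = FALSE),
    rf_num_trees = check_count(rf_num_trees, "rf_num_trees", min = 1L),
    svm_alpha = check_fraction(svm_alpha, "svm_alpha", allow_zero = FALSE),
    svm_epochs = check_count(svm_epochs, "svm_epochs", min = 1L),
    svm_zscore = as.numeric(svm_zscore),
    null_gate_permutations = check_count(null_gate_permutations,
                                         "null_gate_permutations"),
    null_gate_factor = as.numeric(null_gate_factor),
    lr_max_iterations = check_count(lr_max_iterations, "lr_max_iterations",
                                    min = 1L),
    lr_contribution_threshold = check_fraction(lr_contribution_threshold,
                                               "lr_contribution_threshold",
                                               allow_zero = FALSE),
    lr_contribution_mode = match.arg(lr_contribution_mode),
    seed = check_count(seed, "seed")
  ), class = "selector_config")
}

#' @export
print.selector_config <- function(x, ...) {
  cat(sprintf("<selector_config> method=%s seed=%d\n", x$method, x$seed))
  if (x$method == "lr") {
    cat(sprintf("  LBFGS cap=%d, contribution > %.4f (%s)\n",
                x$lr_max_iterations, x$lr_contribution_threshold,
                x$lr_contribution_mode))
  } else {
    cat(sprintf("  %d external iterations, %.0f%% subsamples, retain at >= %.0f%% appearance\n",
                x$external_iterations, 100 * x$subsample_fraction,
                100 * x$appearance_threshold))
  }
  invisible(x)
}

# Stratified subsample: group A (first level) count rounded down, the second
# group takes the remainder of round(fraction * n), so group proportions are
# preserved up to rounding.
stratified_subsample_idx <- function(labels, fraction) {
  lev <- levels(labels)
  idx_a <- which(labels == lev[1L])
  idx_b <- which(labels == lev[2L])
  n_a <- floor(fraction * length(idx_a))
  n_b <- min(length(idx_b),
             max(1L, round(fraction * length(labels)) - n_a))
  sort(c(sample(idx_a, n_a), sample(idx_b, n_b)))
}

#' Per-iteration family selection rule
#'
#' Defines what "selected in one iteration" means for each stability method:
#' for `rf`, families whose Gini importance strictly exceeds the iteration's
#' mean importance (equivalently, whose share of the forest's total impurity
#' reduction exceeds 1/p): trees spread small positive importances over
#' hundreds of uninformative families, so bare positivity is not selective
#' enough to make an appearance count informative. For `svm`,
#' families whose absolute weight sits more than `svm_zscore` standard
#' deviations above the mean of the iteration's |weight| distribution (a
#' distributional cutoff is required because L2-penalised linear weights are
#' dense). A degenerate distribution (zero spread, or all-zero importances)
#' selects nothing.
#'
#' @param importances named numeric vector, one score per family (Gini
#'   importances for rf, raw or absolute weights for svm).
#' @param config a [selector_config()] with method `"rf"` or `"svm"`.
#' @return Character vector of selected family IDs.
#' @export
per_iteration_select <- function(importances, config) {
  stopifnot(inherits(config, "selector_config"))
  if (config$method == "rf") {
    return(names(importances)[importances > mean(importances)])
  }
  if (config$method != "svm") {
    stop("per-iteration selection applies to rf and svm only", call. = FALSE)
  }
  a <- abs(importances)
  s <- sd(a)
  if (!is.finite(s) || s == 0 || all(a == 0)) return(character(0))
  names(a)[(a - mean(a)) / s > config$svm_zscore]
}

#' Run the external stability iterations for rf or svm
#'
#' Each iteration draws a stratified random subsample of
#' `subsample_fraction` of the genomes, refits the configured model on it,
#' extracts per-family importances (Gini importance for rf, absolute linear
#' weights for svm), and applies [per_iteration_select()]. When
#' `null_gate_permutations > 0` the refit is additionally compared against
#' label-permuted refits of the same subsample, and an iteration indistinguishable
#' from label noise selects nothing (see [selector_config()]). The RNG stream
#' of iteration i derives from `config$seed` and i, so the full log is
#' reproducible. A subsample that loses one class (possible only on tiny
#' inputs) is redrawn once, then errors.
#'
#' @param pangenome a labeled `pangenome`.
#' @param config a [selector_config()] with method `"rf"` or `"svm"`.
#' @return An `iteration_log`: a list of records, each with `iteration`,
#'   `selected_families`, `importance` and `subsample_seed`, carrying the
#'   family universe and method as attributes.
#' @export
run_external_iterations <- function(pangenome, config) {
  assert_labeled(pangenome)
  stopifnot(inherits(config, "selector_config"))
  if (!config$method %in% c("rf", "svm")) {
    stop("external iterations apply to rf and svm only; use lr_select()",
         call. = FALSE)
  }
  X <- pangenome$presence
  storage.mode(X) <- "double"
  labels <- pangenome$labels
  records <- vector("list", config$external_iterations)
  for (i in seq_len(config$external_iterations)) {
    iseed <- derive_seed(config$seed, i)
    idx <- withr::with_seed(iseed, stratified_subsample_idx(labels, config$subsample_fraction))
    if (length(unique(labels[idx])) < 2L) {
      iseed <- derive_seed(config$seed, i + 1000000L)
      idx <- withr::with_seed(iseed, stratified_subsample_idx(labels, config$subsample_fraction))
      if (length(unique(labels[idx])) < 2L) {
        stop(sprintf("iteration %d: subsample contains a single class", i),
             call. = FALSE)
      }
    }
    Xs <- X[idx, , drop = FALSE]
    ys <- droplevels(labels[idx])
    fit_importance <- function(y, seed) {
      if (config$method == "rf") {
        fit_rf(Xs, y, num_trees = config$rf_num_trees, seed = seed)$variable.importance
      } else {
        abs(fit_svm_sgd(Xs, y, alpha = config$svm_alpha,
                        epochs = config$svm_epochs, seed = seed)$weights)
      }
    }
    # signal strength: how much evidence the fit carries that the labels are
    # non-random. rf: the best family's impurity reduction. svm: inverse
    # weight scale (separating label noise in a wide matrix needs much
    # larger weights for the same margin).
    strength <- function(imp) {
      if (config$method == "rf") max(imp) else 1 / max(mean(imp), 1e-300)
    }
    imp <- fit_importance(ys, iseed)
    gate_ratio <- Inf
    chance_max <- -Inf
    if (config$null_gate_permutations > 0L) {
      perm_strength <- vapply(seq_len(config$null_gate_permutations),
                              function(k) {
        ps <- derive_seed(iseed, 500L + k)
        yperm <- withr::with_seed(ps, sample(ys))
        strength(fit_importance(yperm, ps))
      }, numeric(1))
      gate_ratio <- strength(imp) / max(perm_strength)
      # for rf the permuted strengths are maximum Gini importances, i.e. the
      # chance-importance scale; families below it are additionally dropped
      # (svm weights cannot be compared across fits this way: their overall
      # scale grows with problem difficulty)
      if (config$method == "rf") chance_max <- max(perm_strength)
    }
    gate_passed <- gate_ratio > config$null_gate_factor
    selected <- if (gate_passed) per_iteration_select(imp, config) else character(0)
    if (gate_passed && config$method == "rf" && is.finite(chance_max)) {
      selected <- selected[imp[selected] > chance_max]
    }
    records[[i]] <- list(iteration = i,
                         selected_families = selected,
                         importance = imp,
                         gate_ratio = gate_ratio,
                         gate_passed = gate_passed,
                         subsample_seed = iseed)
  }
  structure(records, class = "iteration_log",
            family_universe = colnames(X), method = config$method,
            config = config)
}

#' Retain families by appearance frequency across iterations
#'
#' A family's appearance frequency is the fraction of external iterations in
#' which the per-iteration rule selected it; families at or above
#' `appearance_threshold` are retained (the comparison is inclusive).
#'
#' @param records an `iteration_log` from [run_external_iterations()].
#' @param appearance_threshold retention cutoff (default 0.40).
#' @return A `method_selection`: list with `method`, `appearance_frequency`
#'   (named over the full family universe), `retained` and `config_echo`.
#' @export
stability_retain <- function(records, appearance_threshold = 0.40) {
  stopifnot(inherits(records, "iteration_log"), length(records) >= 1L)
  check_fraction(appearance_threshold, "appearance_threshold",
                 allow_zero = FALSE)
  universe <- attr(records, "family_universe")
  freq <- setNames(numeric(length(universe)), universe)
  for (rec in records) {
    sel <- rec$selected_families
    freq[sel] <- freq[sel] + 1
  }
  freq <- freq / length(records)
  retained <- universe[freq >= appearance_threshold]
  cfg <- attr(records, "config")
  structure(list(method = attr(records, "method"),
                 appearance_frequency = freq,
                 retained = retained,
                 config_echo = cfg),
            class = "method_selection")
}

#' LR retention from coefficient contributions
#'
#' Converts logistic-regression coefficients into contribution shares
#' (|coef| / sum of |coef|) and applies one of two retention readings of a
#' "contribution exceeds the threshold" rule:
#' `individual_share` keeps every family whose own share strictly exceeds the
#' threshold (at most `floor(1/threshold)` families can ever qualify);
#' `cumulative_prefix` ranks families by decreasing |coef| and keeps the
#' shortest prefix whose summed share strictly exceeds it. The two readings
#' can differ by orders of magnitude in set size; both are offered because
#' the rule as usually stated does not pin one down.
#'
#' @param coefficients named numeric vector of per-family coefficients.
#' @param threshold contribution threshold as a fraction (default 0.003).
#' @param mode `"individual_share"` or `"cumulative_prefix"`.
#' @return List with `share` (named, summing to 1 unless all coefficients are
#'   zero) and `retained` (character vector).
#' @export
lr_contribution_retain <- function(coefficients, threshold = 0.003,
                                   mode = c("individual_share",
                                            "cumulative_prefix")) {
  mode <- match.arg(mode)
  check_fraction(threshold, "threshold", allow_zero = FALSE)
  a <- abs(coefficients)
  tot <- sum(a)
  if (tot == 0) {
    return(list(share = a, retained = character(0)))
  }
  share <- a / tot
  retained <- if (mode == "individual_share") {
    names(share)[share > threshold]
  } else {
    ord <- order(-share)
    n_keep <- which(cumsum(share[ord]) > threshold)[1L]
    if (is.na(n_keep)) n_keep <- length(ord)
    names(share)[ord[seq_len(n_keep)]]
  }
  list(share = share, retained = retained)
}

#' Feature selection by a single L2-penalised logistic regression
#'
#' Fits one logistic-regression model on the full labeled matrix (LBFGS
#' solver capped at `lr_max_iterations`, L2 penalty) and retains families by
#' [lr_contribution_retain()]. Unlike rf/svm there are no external
#' iterations: the model is fitted once and its coefficient shares play the
#' role of the appearance frequency.
#'
#' @param pangenome a labeled `pangenome`.
#' @param config a [selector_config()] with method `"lr"`.
#' @return A `method_selection` (see [stability_retain()]); its
#'   `appearance_frequency` slot holds the contribution shares.
#' @export
lr_select <- function(pangenome, config) {
  assert_labeled(pangenome)
  stopifnot(inherits(config, "selector_config"), config$method == "lr")
  X <- pangenome$presence
  storage.mode(X) <- "double"
  y01 <- as.numeric(pangenome$labels == levels(pangenome$labels)[2L])
  fit <- fit_lr_ridge(X, y01, max_iter = config$lr_max_iterations)
  res <- lr_contribution_retain(fit$weights,
                                threshold = config$lr_contribution_threshold,
                                mode = config$lr_contribution_mode)
  structure(list(method = "lr",
                 appearance_frequency = res$share,
                 retained = res$retained,
                 config_echo = config),
            class = "method_selection")
}

#' Run one selector end to end
#'
#' Dispatches on `config$method`: `lr` fits once via [lr_select()]; `rf` and
#' `svm` run [run_external_iterations()] followed by [stability_retain()].
#'
#' @param pangenome a labeled `pangenome`.
#' @param config a [selector_config()].
#' @return A `method_selection`; for rf/svm the `iterations` element holds
#'   the full `iteration_log`.
#' @export
select_features <- function(pangenome, config) {
  stopifnot(inherits(config, "selector_config"))
  if (config$method == "lr") return(lr_select(pangenome, config))
  log <- run_external_iterations(pangenome, config)
  sel <- stability_retain(log, config$appearance_threshold)
  sel$iterations <- log
  sel
}

#' @export
print.method_selection <- function(x, ...) {
  cat(sprintf("<method_selection> %s: %d of %d families retained\n",
              x$method, length(x$retained), length(x$appearance_frequency)))
  invisible(x)
}

#' Write a method selection as TSV
#'
#' One row per family: ID, appearance frequency (or contribution share for
#' lr) and a retained flag.
#'
#' @param selection a `method_selection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_selection_tsv <- function(selection, path) {
  stopifnot(inherits(selection, "method_selection"))
  freq <- selection$appearance_frequency
  utils::write.table(
    data.frame(family_id = names(freq),
               appearance_frequency = unname(freq),
               retained = as.integer(names(freq) %in% selection$retained)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an iteration log as JSON lines
#'
#' One JSON object per external iteration (index, subsample seed, selected
#' family IDs) for auditing stability selection.
#'
#' @param records an `iteration_log`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_iteration_log <- function(records, path) {
  stopifnot(inherits(records, "iteration_log"))
  lines <- vapply(records, function(rec) {
    jsonlite::toJSON(list(iteration = rec$iteration,
                          subsample_seed = rec$subsample_seed,
                          selected_families = rec$selected_families),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
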