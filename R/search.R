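#' @name multiplet_search
#' @title Greedy search for redundant and synergistic driver multiplets
#' @description
#' The most redundant multiplet of k drivers maximizes the dynamic
#' O-information toward the target, the most synergistic one minimizes
#' it. An exhaustive search is feasible only for pairs, so the pipeline
#' evaluates all pairs exhaustively at k = 2 and then grows the multiplet
#' greedily one driver at a time. Each addition is vetted against a null
#' of circular-shift surrogates of the newly added series: the addition is
#' accepted when the probability of an increment at least as extreme under
#' the null falls below the (Bonferroni-corrected) threshold. The reported
#' redundancy is the dynamic O-information at the largest accepted size;
#' the synergy is its negation in the synergistic search.
NULL

.mode_better <- function(mode) {
  if (mode == "redundant") function(a, b) a > b else function(a, b) a < b
}

#' Exhaustive search over driver pairs
#'
#' Evaluates the dynamic O-information of every unordered driver pair and
#' returns the extremal one (maximal for `mode = "redundant"`, minimal for
#' `"synergistic"`). Exact ties are broken in favor of the
#' lexicographically smallest index pair, deterministically.
#'
#' @param dataset An [embed_series()] result.
#' @param mode `"redundant"` or `"synergistic"`.
#' @param config An [estimator_config()].
#' @return List with `pair` (original column indices), `names`, `value`
#'   (dΩ2 in bits), and `n_evaluated`.
#' @export
exhaustive_pair_search <- function(dataset,
                                   mode = c("redundant", "synergistic"),
                                   config = estimator_config()) {
  mode <- match.arg(mode)
  nd <- length(dataset$drivers)
  if (nd < 2) stop("pair search needs at least 2 candidate drivers")
  mc <- .measure_ctx(dataset, config)
  better <- .mode_better(mode)
  best <- NULL
  best_val <- NA_real_
  n_eval <- 0L
  for (i in 1:(nd - 1)) {
    for (j in (i + 1):nd) {
      v <- tryCatch(.doi_value(mc, c(i, j)), error = function(e) {
        message(sprintf("skipping pair {%s, %s}: %s",
                        dataset$driver_names[i], dataset$driver_names[j],
                        conditionMessage(e)))
        NA_real_
      })
      n_eval <- n_eval + 1L
      if (is.na(v)) next
      if (is.null(best) || better(v, best_val)) {
        best <- c(i, j)
        best_val <- v
      }
    }
  }
  if (is.null(best)) stop("no driver pair could be evaluated")
  list(pair = dataset$driver_index[best],
       names = dataset$driver_names[best],
       value = best_val,
       n_evaluated = n_eval,
       positions = best)
}

#' Extend a multiplet by one greedy step
#'
#' Evaluates the dynamic O-information of the current multiplet augmented
#' by each remaining candidate and appends the extremal one. Candidates
#' whose evaluation fails (e.g. an exact duplicate of a selected driver
#' making the copula correlation singular) are skipped with a message.
#'
#' @param dataset An [embed_series()] result.
#' @param result A `multiplet_search` object (>= 2 selected drivers).
#' @param config An [estimator_config()].
#' @return The extended `multiplet_search` object; returned unchanged
#'   (with a message) when no candidates remain.
#' @export
greedy_extend <- function(dataset, result, config = estimator_config()) {
  mc <- .measure_ctx(dataset, config)
  sel <- match(result$selected, dataset$driver_index)
  step <- .greedy_step(mc, sel, result$mode, dataset)
  if (is.null(step)) {
    message("no candidate drivers remain; multiplet unchanged")
    return(result)
  }
  result$selected <- c(result$selected, dataset$driver_index[step$pos])
  result$selected_names <- c(result$selected_names,
                             dataset$driver_names[step$pos])
  result$trajectory <- c(result$trajectory, step$value)
  names(result$trajectory) <- paste0("k", 1 + seq_along(result$trajectory))
  result
}

# one greedy addition on a shared context; returns NULL when exhausted
.greedy_step <- function(mc, sel, mode, dataset) {
  cand <- setdiff(seq_along(mc$dcols), sel)
  if (length(cand) == 0) return(NULL)
  better <- .mode_better(mode)
  best <- NULL
  best_val <- NA_real_
  for (cc in cand) {
    v <- tryCatch(.doi_value(mc, c(sel, cc)), error = function(e) {
      message(sprintf("skipping candidate '%s': %s",
                      dataset$driver_names[cc], conditionMessage(e)))
      NA_real_
    })
    if (is.na(v)) next
    if (is.null(best) || better(v, best_val)) {
      best <- cc
      best_val <- v
    }
  }
  if (is.null(best)) return(NULL)
  list(pos = best, value = best_val)
}

# surrogate stopping test for the most recently added driver; does not
# touch the RNG seed (callers manage seeding)
.stopping_core <- function(dataset, mc, sel, traj, mode, config, surr,
                           n_tests) {
  k <- length(sel)
  observed <- if (k == 2) traj[[1]] else traj[[k - 1]] - traj[[k - 2]]
  baseline <- if (k == 2) 0 else traj[[k - 2]]
  shifted_pos <- sel[k]
  dr <- .draw_shifts(surr$n_realizations, dataset, surr)
  cols_k <- mc$dcols[[shifted_pos]]
  null_inc <- vapply(dr$shifts, function(s) {
    emb <- .shifted_embed(dataset, dataset$driver_index[shifted_pos], s,
                          dr$blockwise, dr$trial_bounds)
    mc2 <- mc
    mc2$ctx <- .ctx_replace_cols(mc$ctx, cols_k, emb$state)
    .doi_value(mc2, sel) - baseline
  }, numeric(1))
  r <- if (mode == "redundant") sum(null_inc >= observed)
       else sum(null_inc <= observed)
  p <- (r + 1) / (surr$n_realizations + 1)
  threshold <- as.vector(switch(surr$correction,
                                "bonferroni-step" = surr$alpha / n_tests,
                                "bonferroni-kmax" = surr$alpha / attr(n_tests, "family"),
                                "none" = surr$alpha))
  list(p_value = p, threshold = threshold, accepted = p < threshold,
       observed_increment = observed)
}

#' Surrogate stopping test for the last greedy addition
#'
#' Recomputes the multiplet's dynamic O-information with the most recently
#' added driver circularly shifted (a fresh random shift per realization)
#' and compares the observed increment `dΩ_k - dΩ_{k-1}` against the null
#' increments: larger-or-equal counts for the redundant search,
#' smaller-or-equal for the synergistic one. The add-one p-value is
#' compared against `alpha` divided by the Bonferroni family size of the
#' chosen correction.
#'
#' @param dataset An [embed_series()] result carrying its raw series.
#' @param result A `multiplet_search` object.
#' @param config An [estimator_config()].
#' @param surr A [surrogate_config()].
#' @param n_tests Number of stopping tests in the correction family so
#'   far; defaults to `k - 1` (the pair test counts as the first).
#' @return List with `p_value`, `threshold`, `accepted`, and
#'   `observed_increment`.
#' @export
stopping_test <- function(dataset, result, config = estimator_config(),
                          surr = surrogate_config(), n_tests = NULL) {
  if (is.null(dataset$series)) {
    stop("surrogate testing needs the raw series (weighted distributions have no time axis)")
  }
  sel <- match(result$selected, dataset$driver_index)
  k <- length(sel)
  if (k < 2) stop("stopping test needs at least a selected pair")
  if (is.null(n_tests)) n_tests <- k - 1L
  attr(n_tests, "family") <- n_tests
  mc <- .measure_ctx(dataset, config)
  .seeded(surr$seed,
          .stopping_core(dataset, mc, sel, result$trajectory, result$mode,
                         config, surr, n_tests))
}

#' Greedy multiplet search with surrogate stopping
#'
#' Full pipeline: exhaustive pair search, then greedy one-at-a-time
#' extension up to `k_max`, with a circular-shift surrogate test vetting
#' each addition (including the pair, where the second member of the pair
#' is the shifted series). The search records the trajectory of dΩ_k, the
#' per-step p-values, and `k_stop`, the largest size whose additions were
#' all sequentially accepted (`1` when not even the pair is significant;
#' dΩ_1 = 0 by construction). By default the greedy trajectory is explored
#' all the way to `k_max` so the full profile can be inspected;
#' `stop_at = "rejection"` halts at the first rejected addition instead.
#'
#' @param dataset An [embed_series()] result.
#' @param mode `"redundant"` (maximize dΩ) or `"synergistic"` (minimize).
#' @param config An [estimator_config()].
#' @param surr A [surrogate_config()]; its `seed` makes the whole search
#'   reproducible.
#' @param k_max Largest multiplet size to explore (default 10).
#' @param significance Run the surrogate stopping test at each step
#'   (default `TRUE`). With `FALSE` only the greedy trajectory is
#'   computed and `k_stop` is `NA`.
#' @param stop_at `"kmax"` (default) or `"rejection"`.
#' @return An object of class `multiplet_search`: `mode`, `selected`
#'   (original column indices), `selected_names`, `trajectory` (named
#'   `k2`, `k3`, ...), `step_p_values`, `step_accepted`, `k_stop`,
#'   `reported_value` (dΩ at `k_stop` for the redundant mode, its
#'   negation for the synergistic mode; 0 when `k_stop = 1`).
#' @examples
#' sim <- simulate_toy(toy_model_params(0.7, 0.2, n_steps = 5000, seed = 1))
#' d <- embed_series(sim, m = 1, target = "sigma4")
#' search_multiplets(d, "synergistic", estimator_config("plugin"),
#'                   surrogate_config(n_realizations = 99, seed = 1),
#'                   k_max = 3)
#' @export
search_multiplets <- function(dataset,
                              mode = c("redundant", "synergistic"),
                              config = estimator_config(),
                              surr = surrogate_config(),
                              k_max = 10,
                              significance = TRUE,
                              stop_at = c("kmax", "rejection")) {
  mode <- match.arg(mode)
  stop_at <- match.arg(stop_at)
  k_max <- min(as.integer(k_max), length(dataset$drivers))
  if (k_max < 2) stop("search needs at least 2 candidate drivers")
  family <- k_max - 1L

  .seeded(surr$seed, {
    mc <- .measure_ctx(dataset, config)
    pair <- exhaustive_pair_search(dataset, mode, config)
    sel <- pair$positions
    traj <- pair$value
    p_values <- numeric(0)
    accepted <- logical(0)

    run_test <- function(n_tests_val) {
      nt <- n_tests_val
      attr(nt, "family") <- family
      .stopping_core(dataset, mc, sel, traj, mode, config, surr, nt)
    }

    if (significance) {
      st <- run_test(1L)
      p_values <- st$p_value
      accepted <- st$accepted
    }
    while (length(sel) < k_max &&
           !(stop_at == "rejection" && significance && !accepted[length(accepted)])) {
      step <- .greedy_step(mc, sel, mode, dataset)
      if (is.null(step)) break
      sel <- c(sel, step$pos)
      traj <- c(traj, step$value)
      if (significance) {
        st <- run_test(length(sel) - 1L)
        p_values <- c(p_values, st$p_value)
        accepted <- c(accepted, st$accepted)
      }
    }

    # test j vets multiplet size j + 1; k_stop is the largest size whose
    # additions were all sequentially accepted (1 when the pair fails)
    if (significance) {
      ok <- cumprod(accepted) == 1
      k_stop <- if (any(ok)) max(which(ok)) + 1L else 1L
    } else {
      k_stop <- NA_integer_
    }

    reported <- if (!significance || is.na(k_stop)) {
      v <- traj[length(traj)]
      if (mode == "synergistic") -v else v
    } else if (k_stop < 2) {
      0
    } else {
      v <- traj[k_stop - 1]
      if (mode == "synergistic") -v else v
    }

    names(traj) <- paste0("k", 1 + seq_along(traj))
    structure(list(mode = mode,
                   target = dataset$target_name,
                   selected = dataset$driver_index[sel],
                   selected_names = dataset$driver_names[sel],
                   trajectory = traj,
                   step_p_values = if (significance) p_values else NULL,
                   step_accepted = if (significance) accepted else NULL,
                   k_stop = k_stop,
                   reported_value = reported,
                   alpha = surr$alpha,
                   correction = surr$correction,
                   n_realizations = surr$n_realizations,
                   seed = surr$seed),
              class = "multiplet_search")
  })
}

#' @export
print.multiplet_search <- function(x, ...) {
  cat(sprintf("<multiplet_search> %s search toward '%s'\n", x$mode, x$target))
  k <- 1 + seq_along(x$trajectory)
  added <- c(paste(x$selected_names[1:2], collapse = "+"),
             x$selected_names[-(1:2)])
  tab <- data.frame(k = k,
                    added = added,
                    dOmega_bits = unname(x$trajectory))
  if (!is.null(x$step_p_values)) {
    tab$p_value <- x$step_p_values
    tab$accepted <- x$step_accepted
  }
  print(tab, row.names = FALSE)
  if (!is.na(x$k_stop)) {
    cat(sprintf("k_stop = %d; reported %s = %.6g bits\n", x$k_stop,
                if (x$mode == "synergistic") "synergy" else "redundancy",
                x$reported_value))
  }
  invisible(x)
}
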