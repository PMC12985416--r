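# Sequential model-based (TPE-style) hyperparameter search.
#
# A seeded suggest/observe loop: the first trials are drawn from the prior;
# afterwards observed configurations are split at the gamma-quantile of the
# loss into "good" and "bad" sets, candidates are drawn from a kernel
# density over the good set, and the candidate maximizing the good/bad
# density ratio is evaluated. Minimizes the objective.

#' Declare a hyperparameter dimension
#'
#' @param type One of `"uniform"`, `"loguniform"`, `"int"`, `"categorical"`.
#' @param low,high Bounds (numeric types).
#' @param values Levels (categorical type).
#' @return A parameter definition for [tpe_optimize()].
#' @export
param_def <- function(type = c("uniform", "loguniform", "int", "categorical"),
                      low = NULL, high = NULL, values = NULL) {
  type <- arg_match(type)
  if (type == "categorical") {
    if (is.null(values) || length(values) < 1) abort("categorical needs `values`")
  } else {
    if (is.null(low) || is.null(high) || low > high) abort("invalid bounds")
    if (type == "loguniform" && low <= 0) abort("loguniform needs low > 0")
  }
  list(type = type, low = low, high = high, values = values)
}

tpe_sample_prior <- function(def) {
  switch(def$type,
    uniform = runif(1, def$low, def$high),
    loguniform = exp(runif(1, log(def$low), log(def$high))),
    int = sample(seq(def$low, def$high), 1),
    categorical = sample(def$values, 1)
  )
}

# draw one value from the Parzen mixture over `obs` for a numeric dimension
tpe_sample_good <- function(def, obs) {
  span <- if (def$type == "loguniform") log(def$high) - log(def$low)
          else def$high - def$low
  bw <- max(span / sqrt(length(obs) + 1), span * 0.01)
  center <- obs[sample.int(length(obs), 1)]
  if (def$type == "loguniform") {
    x <- exp(min(max(rnorm(1, log(center), bw), log(def$low)), log(def$high)))
  } else {
    x <- min(max(rnorm(1, center, bw), def$low), def$high)
  }
  if (def$type == "int") x <- as.integer(round(x)) else x
}

tpe_log_density <- function(def, obs, x) {
  if (def$type == "categorical") {
    counts <- table(factor(obs, levels = def$values))
    return(log((counts[[as.character(x)]] + 1) /
                 (length(obs) + length(def$values))))
  }
  span <- if (def$type == "loguniform") log(def$high) - log(def$low)
          else def$high - def$low
  bw <- max(span / sqrt(length(obs) + 1), span * 0.01)
  xx <- if (def$type == "loguniform") log(x) else x
  oo <- if (def$type == "loguniform") log(obs) else obs
  log(mean(dnorm(xx, oo, bw)) + 1e-12)
}

#' TPE-style sequential hyperparameter optimization
#'
#' @param objective Function taking a named parameter list, returning a
#'   scalar loss to minimize.
#' @param space Named list of [param_def()]s.
#' @param n_trials Total evaluations (at least 1).
#' @param seed Integer seed; the whole loop is deterministic given it.
#' @param n_startup Random trials before the density model engages.
#' @param gamma Quantile splitting good from bad trials.
#' @param n_candidates Candidates scored per suggestion.
#' @return List with `best_params`, `best_loss` and a `trials` tibble.
#' @export
tpe_optimize <- function(objective, space, n_trials, seed = 1L,
                         n_startup = 10L, gamma = 0.25, n_candidates = 24L) {
  if (n_trials < 1) abort("`n_trials` must be at least 1")
  set.seed(seed)
  params_hist <- vector("list", n_trials)
  losses <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    if (t <= n_startup) {
      cand <- lapply(space, tpe_sample_prior)
    } else {
      n_good <- max(1L, ceiling(gamma * (t - 1)))
      ord <- order(losses[seq_len(t - 1)])
      good <- ord[seq_len(n_good)]
      bad <- ord[-seq_len(n_good)]
      if (length(bad) == 0) bad <- good
      best_score <- -Inf
      cand <- NULL
      for (k in seq_len(n_candidates)) {
        trial <- imap(space, function(def, nm) {
          gobs <- map(params_hist[good], nm)
          gobs <- unlist(gobs)
          if (def$type == "categorical") {
            counts <- table(factor(gobs, levels = def$values)) + 1
            sample(def$values, 1, prob = as.numeric(counts))
          } else tpe_sample_good(def, gobs)
        })
        score <- sum(unlist(imap(space, function(def, nm) {
          gobs <- unlist(map(params_hist[good], nm))
          bobs <- unlist(map(params_hist[bad], nm))
          tpe_log_density(def, gobs, trial[[nm]]) -
            tpe_log_density(def, bobs, trial[[nm]])
        })))
        if (score > best_score) {
          best_score <- score
          cand <- trial
        }
      }
    }
    params_hist[[t]] <- cand
    losses[t] <- objective(cand)
  }
  best <- which.min(losses)
  list(best_params = params_hist[[best]], best_loss = losses[best],
       trials = tibble(trial = seq_len(n_trials), loss = losses,
                       params = params_hist))
}
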