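#' Hyperparameter-space dimension constructors
#'
#' Building blocks for the spaces searched by [bayesian_optimize()]:
#' continuous (optionally log-scaled), integer and categorical dimensions.
#'
#' @param name Parameter name.
#' @param min,max Bounds (inclusive).
#' @param log Sample/model the dimension on the log scale.
#' @param levels Character vector of categorical choices.
#' @return A `bo_dim` list.
#' @name bo_dims
NULL

#' @rdname bo_dims
#' @export
bo_real <- function(name, min, max, log = FALSE) {
  structure(list(name = name, type = "real", min = min, max = max, log = log),
            class = "bo_dim")
}

#' @rdname bo_dims
#' @export
bo_int <- function(name, min, max) {
  structure(list(name = name, type = "int", min = min, max = max),
            class = "bo_dim")
}

#' @rdname bo_dims
#' @export
bo_cat <- function(name, levels) {
  structure(list(name = name, type = "cat", levels = levels),
            class = "bo_dim")
}

#' Hyperparameter spaces of the supported learning methods
#'
#' The named hyperparameters per method follow the published tuning list
#' for each classifier family: the boosted-tree space (leaf count,
#' positive-class weight, leaf occupancy, binning, hessian floor, bagging
#' and feature-sampling fractions), the MLP space (hidden width, learning
#' rate schedule and initial value, iteration cap, tolerance) and the SVM
#' space (C, gamma, polynomial degree, kernel in linear/poly/rbf).  The
#' numeric ranges are standard practitioner ranges; the vignette lists
#' each with its rationale.
#'
#' @param model `"gbt"`, `"mlp"` or `"svm"`.
#' @return List of [bo_dims] dimensions.
#' @export
hp_space <- function(model = c("gbt", "mlp", "svm")) {
  model <- match.arg(model)
  switch(model,
    gbt = list(
      bo_int("num_leaves", 2, 128),
      bo_real("scale_pos_weight", 0.5, 10, log = TRUE),
      bo_int("min_child_samples", 5, 100),
      bo_int("bin_construct_sample_cnt", 1000, 200000),
      bo_int("max_bin", 32, 255),
      bo_real("min_sum_hessian_in_leaf", 1e-3, 10, log = TRUE),
      bo_real("bagging_fraction", 0.5, 1),
      bo_real("feature_fraction", 0.5, 1),
      bo_real("feature_fraction_bynode", 0.5, 1)),
    mlp = list(
      bo_int("hidden_layer_sizes", 2, 50),
      bo_cat("learning_rate", c("constant", "invscaling", "adaptive")),
      bo_real("learning_rate_init", 1e-4, 1e-1, log = TRUE),
      bo_int("max_iter", 50, 500),
      bo_real("tol", 1e-6, 1e-2, log = TRUE)),
    svm = list(
      bo_real("C", 1e-2, 1e3, log = TRUE),
      bo_real("gamma", 1e-4, 10, log = TRUE),
      bo_int("degree", 2, 5),
      bo_cat("kernel", c("linear", "poly", "rbf"))))
}

bo_sample_point <- function(space) {
  out <- map(space, function(d) {
    switch(d$type,
      real = if (isTRUE(d$log)) {
        exp(runif(1, log(d$min), log(d$max)))
      } else {
        runif(1, d$min, d$max)
      },
      int = sample(seq(d$min, d$max), 1),
      cat = sample(d$levels, 1))
  })
  setNames(out, map_chr(space, "name"))
}

# encode a hyperparameter point into the GP's unit-cube input space
bo_encode <- function(space, h) {
  unlist(map(space, function(d) {
    v <- h[[d$name]]
    switch(d$type,
      real = if (isTRUE(d$log)) {
        (log(v) - log(d$min)) / (log(d$max) - log(d$min))
      } else {
        (v - d$min) / (d$max - d$min)
      },
      int = if (d$max > d$min) (v - d$min) / (d$max - d$min) else 0.5,
      cat = as.numeric(d$levels == v))
  }))
}

matern52 <- function(r) (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)

gp_fit <- function(X, y) {
  ys <- sd(y)
  ym <- mean(y)
  yz <- if (ys > 0) (y - ym) / ys else y * 0
  D <- as.matrix(stats::dist(X))
  best <- NULL
  for (ell in c(0.1, 0.2, 0.5, 1, 2)) {
    for (sn in c(1e-6, 1e-4, 1e-2)) {
      K <- matern52(D / ell) + diag(sn, nrow(X))
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), yz))
      ll <- -0.5 * sum(yz * alpha) - sum(log(diag(ch)))
      if (is.null(best) || ll > best$ll) {
        best <- list(ll = ll, ell = ell, chol = ch, alpha = alpha,
                     X = X, ym = ym, ys = ys)
      }
    }
  }
  best
}

gp_predict <- function(gp, Xnew) {
  r <- sqrt(outer(rowSums(Xnew^2), rowSums(gp$X^2), "+") -
              2 * Xnew %*% t(gp$X))
  r[!is.finite(r) | r < 0] <- 0
  Ks <- matern52(r / gp$ell)
  mu <- drop(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$chol), t(Ks))
  s2 <- pmax(1 + 1e-6 - colSums(v^2), 1e-12)
  list(mu = mu * ifelse(gp$ys > 0, gp$ys, 1) + gp$ym,
       sd = sqrt(s2) * ifelse(gp$ys > 0, gp$ys, 1))
}

#' Gaussian-process Bayesian hyperparameter optimization
#'
#' Minimizes a (log-loss) objective over a hyperparameter space.  The
#' search first evaluates `n_init` random points, then repeatedly fits a
#' Gaussian-process surrogate (Matern-5/2 kernel over the unit-cube
#' encoding of the space, length-scale and noise picked by marginal
#' likelihood) and evaluates the candidate with the highest expected
#' improvement, for `n_iter` further evaluations.  The returned point is
#' the one with the global-minimum observed loss.
#'
#' An objective that raises an error or returns a non-finite value is
#' recorded as a failed evaluation with `Inf` loss and the optimization
#' continues (failed losses enter the surrogate as the worst finite loss
#' observed so far).
#'
#' @param space List of [bo_dims] dimensions (e.g. [hp_space()]).
#' @param objective Function taking a named list of hyperparameter values
#'   and returning a finite loss.
#' @param n_init Random initial evaluations.
#' @param n_iter Surrogate-guided evaluations after initialization.
#' @param n_candidates Random candidate points scored per iteration.
#' @param seed Integer seed.
#' @return A `mult_bo` list: `best` (named hyperparameter list),
#'   `best_loss`, and `trace` (tibble with one row per evaluation:
#'   `iter`, `phase`, `loss`, plus one column per hyperparameter).
#' @export
bayesian_optimize <- function(space, objective, n_init = 10, n_iter = 50,
                              n_candidates = 256, seed = 1) {
  nm <- map_chr(space, "name")
  if (anyDuplicated(nm)) abort("duplicate hyperparameter names")
  points <- list()
  losses <- numeric(0)
  eval_point <- function(h) {
    val <- tryCatch(objective(h), error = function(e) Inf)
    if (!is.finite(val)) val <- Inf
    val
  }
  with_seed(seed, {
    for (j in seq_len(n_init)) {
      h <- bo_sample_point(space)
      points[[length(points) + 1]] <- h
      losses <- c(losses, eval_point(h))
    }
    for (j in seq_len(n_iter)) {
      X <- do.call(rbind, map(points, ~ bo_encode(space, .x)))
      y <- losses
      if (all(!is.finite(y))) {
        h <- bo_sample_point(space)
      } else {
        worst <- max(y[is.finite(y)])
        y[!is.finite(y)] <- worst
        gp <- gp_fit(X, y)
        cand <- map(seq_len(n_candidates), ~ bo_sample_point(space))
        Xc <- do.call(rbind, map(cand, ~ bo_encode(space, .x)))
        if (is.null(gp)) {
          h <- cand[[1]]
        } else {
          pr <- gp_predict(gp, Xc)
          y_best <- min(y)
          z <- (y_best - pr$mu) / pr$sd
          ei <- (y_best - pr$mu) * stats::pnorm(z) + pr$sd * stats::dnorm(z)
          h <- cand[[which.max(ei)]]
        }
      }
      points[[length(points) + 1]] <- h
      losses <- c(losses, eval_point(h))
    }
  })
  best_i <- which.min(losses)
  trace <- bind_cols(
    tibble(iter = seq_along(losses),
           phase = rep(c("random", "surrogate"), c(n_init, n_iter)),
           loss = losses),
    bind_rows(map(points, ~ as_tibble(map(.x, ~ .x)))))
  structure(list(best = points[[best_i]], best_loss = losses[best_i],
                 trace = trace),
            class = "mult_bo")
}

#' @export
print.mult_bo <- function(x, ...) {
  cat("<mult_bo> ", nrow(x$trace), " evaluations, best loss ",
      signif(x$best_loss, 5), "\n", sep = "")
  invisible(x)
}

#' @rdname bayesian_optimize
#' @param x A `mult_bo` result.
#' @param ... Unused.
#' @export
tidy.mult_bo <- function(x, ...) x$trace

#' @rdname bayesian_optimize
#' @param object A `mult_bo` result.
#' @export
autoplot.mult_bo <- function(object, ...) {
  tr <- mutate(object$trace,
               running_min = cummin(ifelse(is.finite(.data$loss),
                                           .data$loss, NA_real_)))
  ggplot(tr, aes(x = .data$iter)) +
    geom_point(aes(y = .data$loss, colour = .data$phase)) +
    geom_line(aes(y = .data$running_min)) +
    labs(x = "evaluation", y = "log loss",
         title = "Bayesian optimization trace") +
    theme_minimal()
}
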