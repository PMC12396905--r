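#' Factorial study design grid
#'
#' Enumerates the per-subject simulation plan: 2 cartilage models x
#' 3 gait loading profiles x 7 quasistatic instances x pre/post
#' treatment (84 instance solves per subject, 6 unique scenarios).
#'
#' @return data.frame with columns `cartilage`, `glp`, `instance`,
#'   `treatment`.
#' @export
enumerate_instance_grid <- function() {
  expand.grid(
    cartilage = c("nishii", "shivanna"),
    glp = c("bergmann_like", "harris_like", "skalshoi_like"),
    instance = 1:7,
    treatment = c("pre", "post"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
}

#' Scenario set
#'
#' @return data.frame of the 6 unique simulation scenarios (cartilage
#'   model x gait loading profile).
#' @export
scenario_grid <- function() {
  expand.grid(
    cartilage = c("nishii", "shivanna"),
    glp = c("bergmann_like", "harris_like", "skalshoi_like"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
}

#' Build the DEA model for one hip and cartilage model
#'
#' Meshes the hip, generates both cartilage layers (acetabular layer per
#' the requested model, femoral layer always via the radial-offset
#' model) and assembles the spring bed.
#'
#' @param geom a [hip_geometry()].
#' @param cartilage `"shivanna"` or `"nishii"`.
#' @param seed mesh seed.
#' @param thickness_map map for the `"nishii"` model.
#' @param mat a [material_params()].
#' @return A [dea_model()].
#' @export
build_hip_model <- function(geom, cartilage = c("shivanna", "nishii"),
                            seed = 1L, thickness_map = default_thickness_map(),
                            mat = material_params()) {
  cartilage <- match.arg(cartilage)
  cup <- generate_acetabulum(geom, seed)
  head <- generate_femoral_head(geom, seed)
  acet <- if (cartilage == "shivanna") {
    shivanna_offset(cup$surface, cup$frame, shivanna_params(), "acetabular")
  } else {
    nishii_offset(cup$surface, cup$frame, thickness_map)
  }
  fem <- shivanna_offset(head$surface, head$frame, shivanna_params(),
                         "femoral")
  dea_model(acet, fem, cup$frame, mat)
}

#' Run the factorial simulation study on a cohort
#'
#' For every hip, scenario (cartilage model x gait loading profile) and
#' treatment (pre/post), solves the seven-instance gait sequence and
#' computes the eight stress metrics. Diverging sequences are recorded
#' and carry no metrics (the whole sequence is excluded, never single
#' instances).
#'
#' @param cohort a [generate_cohort()] result.
#' @param glps named list of [gait_profile()]s; defaults to the three
#'   synthetic families.
#' @param settings a [solver_settings()].
#' @param stance_duration s, time scale of the dose metrics.
#' @param thresholds a [metric_thresholds()].
#' @param seed seed forwarded to mesh generation.
#' @param thickness_map map for the dysplastic cartilage model.
#' @param progress print per-hip progress.
#' @return object of class `study_result`: `metrics` (data.frame, one
#'   row per hip x scenario x treatment with metrics or NA),
#'   `divergences` (data.frame of failed sequences), `manifest` (the
#'   cohort manifest).
#' @export
run_study <- function(cohort, glps = NULL,
                      settings = solver_settings(),
                      stance_duration = 0.6,
                      thresholds = metric_thresholds(),
                      seed = 1L,
                      thickness_map = default_thickness_map(),
                      progress = FALSE) {
  if (is.null(glps)) {
    glps <- list(
      bergmann_like = synth_glp("bergmann_like", seed = seed),
      harris_like = synth_glp("harris_like", seed = seed),
      skalshoi_like = synth_glp("skalshoi_like", seed = seed)
    )
  }
  scen <- scenario_grid()
  rows <- list()
  divs <- list()
  for (h in cohort) {
    if (progress) message("hip ", h$hip_id)
    for (tr in c("pre", "post")) {
      geom <- h[[paste0(tr, "_geometry")]]
      models <- list(
        shivanna = build_hip_model(geom, "shivanna", seed, thickness_map),
        nishii = build_hip_model(geom, "nishii", seed, thickness_map)
      )
      for (sc in seq_len(nrow(scen))) {
        glp <- glps[[scen$glp[sc]]]
        inst <- discretize_gait(glp, h$weight, stance_duration)
        out <- solve_sequence(models[[scen$cartilage[sc]]], inst, settings)
        base <- data.frame(
          hip_id = h$hip_id, subject_id = h$subject_id,
          cartilage = scen$cartilage[sc], glp = scen$glp[sc],
          scenario = paste(scen$cartilage[sc], scen$glp[sc], sep = "."),
          treatment = tr, stringsAsFactors = FALSE
        )
        if (inherits(out, "sequence_divergence")) {
          base$converged <- FALSE
          for (mn in stress_metric_names()) base[[mn]] <- NA_real_
          divs[[length(divs) + 1L]] <- cbind(
            base[c("hip_id", "subject_id", "scenario", "treatment")],
            failed_instances = paste(out$failed, collapse = ";")
          )
        } else {
          base$converged <- TRUE
          met <- compute_stress_metrics(out, thresholds)
          for (mn in names(met)) base[[mn]] <- met[[mn]]
        }
        rows[[length(rows) + 1L]] <- base
      }
    }
  }
  structure(list(
    metrics = do.call(rbind, rows),
    divergences = if (length(divs) > 0L) do.call(rbind, divs) else
      data.frame(hip_id = character(0), subject_id = character(0),
                 scenario = character(0), treatment = character(0),
                 failed_instances = character(0)),
    manifest = cohort_manifest(cohort)
  ), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "study_result: %d sequences (%d converged, %d diverged) over %d hips, %d scenarios\n",
    nrow(x$metrics), sum(x$metrics$converged), nrow(x$divergences),
    length(unique(x$metrics$hip_id)), length(unique(x$metrics$scenario))
  ))
  invisible(x)
}

#' Paired (dependent-samples) t test
#'
#' Classical paired t on post - pre differences, two-sided. Zero-variance
#' differences are handled explicitly: identical samples give t = 0,
#' p = 1; constant nonzero differences are flagged and reported with
#' p = 0.
#'
#' @param pre,post paired numeric vectors.
#' @return list with `t`, `p`, `mean_diff`, `n`, `flag`.
#' @export
paired_t <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 2L) stop("paired t test needs at least 2 pairs")
  d <- post - pre
  md <- mean(d)
  if (stats::sd(d) <= 1e-12 * max(abs(md), 1)) {
    if (md == 0) return(list(t = 0, p = 1, mean_diff = 0, n = n,
                             flag = "zero_variance_zero_mean"))
    return(list(t = sign(md) * Inf, p = 0, mean_diff = md, n = n,
                flag = "zero_variance_nonzero_mean"))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = md, n = n,
       flag = "ok")
}

#' Weighted Pearson correlation
#'
#' Correlation from weighted means and covariances; the p value uses a t
#' transform with the Kish effective sample size
#' n_eff = (sum w)^2 / sum w^2.
#'
#' @param x,y numeric vectors.
#' @param w positive weights (default equal: ordinary Pearson).
#' @return list with `r`, `p`, `n_eff`.
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x))
  ok <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (any(w <= 0)) stop("weights must be positive")
  if (length(x) < 3L) stop("need at least 3 observations")
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  if (vx == 0 || vy == 0)
    return(list(r = NA_real_, p = NA_real_, n_eff = sw^2 / sum(w^2)))
  r <- sum(w * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
  n_eff <- sw^2 / sum(w^2)
  r_cl <- min(1 - 1e-15, max(-1 + 1e-15, r))
  tstat <- r_cl * sqrt((n_eff - 2) / (1 - r_cl^2))
  p <- 2 * stats::pt(-abs(tstat), df = max(1, n_eff - 2))
  list(r = r, p = p, n_eff = n_eff)
}

#' Correlation grid between stress metrics and radiographic measures
#'
#' For every scenario, metric and radiographic measure, the weighted
#' Pearson correlation over the pooled pre- and post-operative converged
#' hips. Weights equalize the group sums: every pre-operative pair
#' carries weight W/n_pre and every post-operative pair W/n_post, so
#' uneven convergence does not skew the pooled correlation.
#'
#' @param study a [run_study()] result.
#' @param measures character vector of radiographic measures.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame with one row per (scenario, metric, measure):
#'   `r`, `p`, `n`, `significant`, `missing`.
#' @export
correlation_grid <- function(study,
                             measures = c("LCEA", "AI", "FHEI", "ACEA", "AAA"),
                             alpha = 0.05) {
  stopifnot(inherits(study, "study_result"))
  met <- study$metrics
  man <- study$manifest
  scens <- sort(unique(met$scenario))
  out <- list()
  for (sc in scens) {
    for (mn in stress_metric_names()) {
      for (ms in measures) {
        rows_pre <- met[met$scenario == sc & met$treatment == "pre" &
                          met$converged, ]
        rows_post <- met[met$scenario == sc & met$treatment == "post" &
                           met$converged, ]
        x_pre <- man[[paste0(ms, "_pre")]][match(rows_pre$hip_id, man$hip_id)]
        x_post <- man[[paste0(ms, "_post")]][match(rows_post$hip_id, man$hip_id)]
        x <- c(x_pre, x_post)
        y <- c(rows_pre[[mn]], rows_post[[mn]])
        n_pre <- nrow(rows_pre); n_post <- nrow(rows_post)
        cell <- data.frame(scenario = sc, metric = mn, measure = ms,
                           r = NA_real_, p = NA_real_,
                           n = n_pre + n_post,
                           significant = FALSE, missing = FALSE,
                           stringsAsFactors = FALSE)
        if (n_pre >= 2L && n_post >= 2L && n_pre + n_post >= 3L) {
          w <- c(rep(1 / n_pre, n_pre), rep(1 / n_post, n_post))
          wp <- weighted_pearson(x, y, w)
          cell$r <- wp$r; cell$p <- wp$p
          cell$significant <- is.finite(wp$p) && wp$p < alpha
        } else {
          cell$missing <- TRUE
        }
        out[[length(out) + 1L]] <- cell
      }
    }
  }
  do.call(rbind, out)
}

#' Forward stepwise regression with F-to-enter / F-to-remove
#'
#' Classical forward stepwise selection: at each step the candidate with
#' the largest partial F enters if it reaches `f_in`; after every entry,
#' any entered variable whose partial F has dropped below `f_out` is
#' removed. Perfectly collinear candidates are barred from entry.
#'
#' @param y response vector.
#' @param X data.frame of candidate predictors (numeric; encode factors
#'   beforehand, e.g. sex as 0/1).
#' @param f_in F-to-enter threshold.
#' @param f_out F-to-remove threshold.
#' @return list with `terms` (selected, in entry order), `model` (the
#'   final [stats::lm()] fit), `steps` (data.frame: step, action, term,
#'   r_squared, r_squared_change), `barred` (collinear candidates).
#' @export
forward_stepwise <- function(y, X, f_in = 3.84, f_out = 2.71) {
  stopifnot(is.data.frame(X), f_in > f_out, f_out >= 0)
  ok <- is.finite(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  terms <- character(0)
  barred <- character(0)
  steps <- list()
  r2_prev <- 0
  fit_rss <- function(tms) {
    if (length(tms) == 0L) return(list(rss = sum((y - mean(y))^2), rank = 1L))
    fit <- stats::lm(y ~ ., data = X[, tms, drop = FALSE])
    list(rss = sum(stats::residuals(fit)^2),
         rank = fit$rank, fit = fit)
  }
  repeat {
    cur <- fit_rss(terms)
    cand <- setdiff(names(X), c(terms, barred))
    if (length(cand) == 0L) break
    f_vals <- vapply(cand, function(v) {
      trial <- fit_rss(c(terms, v))
      if (trial$rank < length(terms) + 2L) return(NA_real_)  # collinear
      df2 <- n - trial$rank
      if (df2 < 1L || trial$rss <= 0) return(Inf)
      (cur$rss - trial$rss) / (trial$rss / df2)
    }, 0)
    newly_barred <- cand[is.na(f_vals)]
    if (length(newly_barred) > 0L) barred <- c(barred, newly_barred)
    f_vals <- f_vals[!is.na(f_vals)]
    if (length(f_vals) == 0L || max(f_vals) < f_in) break
    enter <- names(which.max(f_vals))
    terms <- c(terms, enter)
    cur <- fit_rss(terms)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - cur$rss / tss
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, action = "enter", term = enter,
      r_squared = r2, r_squared_change = r2 - r2_prev,
      stringsAsFactors = FALSE
    )
    r2_prev <- r2
    # removal pass
    repeat {
      if (length(terms) == 0L) break
      f_rm <- vapply(terms, function(v) {
        red <- fit_rss(setdiff(terms, v))
        full <- fit_rss(terms)
        df2 <- n - full$rank
        if (df2 < 1L || full$rss <= 0) return(Inf)
        (red$rss - full$rss) / (full$rss / df2)
      }, 0)
      if (min(f_rm) >= f_out) break
      drop_v <- names(which.min(f_rm))
      terms <- setdiff(terms, drop_v)
      cur <- fit_rss(terms)
      r2 <- if (length(terms) == 0L) 0 else 1 - cur$rss / sum((y - mean(y))^2)
      steps[[length(steps) + 1L]] <- data.frame(
        step = length(steps) + 1L, action = "remove", term = drop_v,
        r_squared = r2, r_squared_change = r2 - r2_prev,
        stringsAsFactors = FALSE
      )
      r2_prev <- r2
    }
  }
  final <- if (length(terms) > 0L)
    stats::lm(y ~ ., data = X[, terms, drop = FALSE]) else stats::lm(y ~ 1)
  list(
    terms = terms,
    model = final,
    steps = if (length(steps) > 0L) do.call(rbind, steps) else
      data.frame(step = integer(0), action = character(0),
                 term = character(0), r_squared = numeric(0),
                 r_squared_change = numeric(0)),
    barred = barred
  )
}

#' Pre/post treatment effects per metric and scenario
#'
#' For hips converged in both treatments of a scenario: mean pre, mean
#' post, relative change 100 (post - pre)/pre, and the paired-t p value;
#' plus a cross-scenario aggregate (plain mean of the relative changes).
#'
#' @param study a [run_study()] result.
#' @return list with `by_scenario` and `aggregate` data.frames.
#' @export
summarize_treatment_effects <- function(study) {
  stopifnot(inherits(study, "study_result"))
  met <- study$metrics
  scens <- sort(unique(met$scenario))
  rows <- list()
  for (sc in scens) {
    pre <- met[met$scenario == sc & met$treatment == "pre" & met$converged, ]
    post <- met[met$scenario == sc & met$treatment == "post" & met$converged, ]
    shared <- intersect(pre$hip_id, post$hip_id)
    if (length(shared) == 0L) next
    pre <- pre[match(shared, pre$hip_id), ]
    post <- post[match(shared, post$hip_id), ]
    for (mn in stress_metric_names()) {
      mp <- mean(pre[[mn]]); mq <- mean(post[[mn]])
      pt <- if (length(shared) >= 2L) paired_t(pre[[mn]], post[[mn]]) else
        list(p = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, metric = mn, n_paired = length(shared),
        mean_pre = mp, mean_post = mq,
        relative_change = if (mp != 0) 100 * (mq - mp) / mp else NA_real_,
        p = pt$p, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) stop("no paired converged hips in any scenario")
  by_scenario <- do.call(rbind, rows)
  agg <- stats::aggregate(relative_change ~ metric, by_scenario, mean)
  list(by_scenario = by_scenario, aggregate = agg)
}
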