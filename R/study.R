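#' Configuration for a simulation study run
#'
#' Bundles a study design with the administration and pattern-detection
#' settings and the replication plan. All randomness flows from
#' `base_seed`: replication r seeds the R stream with `base_seed + r`
#' and then draws, in order, the item pool, the abilities, the group
#' assignment and the response uniforms, so every replication is
#' independently reproducible.
#'
#' @param design a [study_design()] or [design_preset()] result.
#' @param criterion item selection criterion, `"D"` or `"bayesA"`.
#' @param stopping [stopping_fixed()] or [stopping_variable()]; defaults
#'   to fixed length at the design's `Z0`.
#' @param grid [lambda_grid()] for the pattern-detection step.
#' @param replications number of Monte Carlo replications.
#' @param base_seed integer base seed.
#' @param bic_mode,selection_mode see [path_fit()] and
#'   [select_optimal_patterns()].
#' @param prior_mode `"identity"` uses a standard-normal prior for MAP
#'   scoring and Bayesian A-optimality; `"true"` uses the generating
#'   ability covariance.
#' @param theta_source trait scores fed to the L1 step: `"estimate"`
#'   (MCAT MAP estimates), `"true"` (generating abilities; skips the
#'   adaptive test entirely), or `"both"` (adds benchmark columns with
#'   suffix `_true`).
#' @param pattern_step set `FALSE` to skip pattern detection (e.g. when
#'   only ability-recovery or exposure indices are needed).
#' @return Object of class `run_config`.
#' @export
run_config <- function(design, criterion = c("D", "bayesA"),
                       stopping = NULL, grid = lambda_grid(),
                       replications = 5L, base_seed = 1L,
                       bic_mode = c("refit", "shrunken"),
                       selection_mode = c("joint", "per_item"),
                       prior_mode = c("identity", "true"),
                       theta_source = c("estimate", "true", "both"),
                       pattern_step = TRUE) {
  stopifnot(inherits(design, "study_design"))
  criterion <- match.arg(criterion)
  bic_mode <- match.arg(bic_mode)
  selection_mode <- match.arg(selection_mode)
  prior_mode <- match.arg(prior_mode)
  theta_source <- match.arg(theta_source)
  if (is.null(stopping)) stopping <- stopping_fixed(design$Z0)
  stopifnot(stopping$type %in% c("fixed", "variable"))
  replications <- as.integer(replications)
  if (replications < 1L) stop("'replications' must be at least 1")
  structure(list(design = design, criterion = criterion,
                 stopping = stopping, grid = grid,
                 replications = replications,
                 base_seed = as.integer(base_seed),
                 bic_mode = bic_mode, selection_mode = selection_mode,
                 prior_mode = prior_mode, theta_source = theta_source,
                 pattern_step = isTRUE(pattern_step)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: %s selection, %s stopping, %d replications (base seed %d)\n",
              x$criterion,
              if (x$stopping$type == "fixed")
                sprintf("fixed Z0 = %d", x$stopping$Z0)
              else sprintf("variable SE <= %.2f max %d", x$stopping$se,
                           x$stopping$max_items),
              x$replications, x$base_seed))
  cat(sprintf("  scores: %s; BIC: %s/%s; prior: %s\n", x$theta_source,
              x$bic_mode, x$selection_mode, x$prior_mode))
  print(x$design)
  invisible(x)
}

# pattern detection + refit + indices for one score source
.pattern_indices <- function(pool, assignment, scores, config) {
  rep_ids <- replenished_ids(pool)
  resp <- config$.replenished
  paths <- lapply(as.character(rep_ids), function(id)
    path_fit(resp[[id]]$responses,
             scores[resp[[id]]$examinees, , drop = FALSE],
             grid = config$grid, bic_mode = config$bic_mode))
  sel <- suppressWarnings(
    select_optimal_patterns(paths, mode = config$selection_mode))
  refits <- lapply(seq_along(rep_ids), function(j)
    refit_item(resp[[as.character(rep_ids[j])]]$responses,
               scores[resp[[as.character(rep_ids[j])]]$examinees, ,
                      drop = FALSE],
               sel$Q_hat[j, ]))
  a_hat <- do.call(rbind, lapply(refits, `[[`, "a"))
  b_hat <- vapply(refits, `[[`, numeric(1), "b")
  err <- ame_item(pool$a[rep_ids, , drop = FALSE], a_hat,
                  pool$b[rep_ids], b_hat)
  list(csr = csr(pool$Q[rep_ids, , drop = FALSE], sel$Q_hat),
       ame_a = err$a, ame_b = err$b)
}

#' Run one seeded replication of a study
#'
#' Executes the full pipeline for replication `rep_index`: generate the
#' pool, abilities and group assignment; administer the MCAT cohort
#' (unless `theta_source = "true"`); run the penalty path and BIC
#' selection for every replenished item; refit item parameters under the
#' detected patterns; and compute all evaluation indices.
#'
#' @param config a [run_config()].
#' @param rep_index replication number (seeds the R stream with
#'   `base_seed + rep_index`).
#' @return One-row data frame with `rep`, `seed`, `csr`, `ame_theta`,
#'   `rmse_theta`, `ame_a`, `ame_b`, `chi_square`, `tor`, `mean_length`
#'   (benchmark columns `csr_true`, `ame_a_true`, `ame_b_true` are added
#'   when `theta_source = "both"`). Indices that do not apply to the
#'   configuration are `NA`.
#' @export
run_replication <- function(config, rep_index) {
  stopifnot(inherits(config, "run_config"))
  seed <- (config$base_seed + as.integer(rep_index)) %% 2147483647L
  set.seed(seed)
  design <- config$design
  pool <- generate_item_pool(design)
  abilities <- generate_abilities(design$N, design$ability_cov)
  assignment <- make_group_assignment(design)
  prior <- if (config$prior_mode == "true")
    prior_spec(cov = design$ability_cov) else prior_spec(design$K)
  need_mcat <- config$theta_source %in% c("estimate", "both")
  row <- data.frame(rep = rep_index, seed = seed, csr = NA_real_,
                    ame_theta = NA_real_, rmse_theta = NA_real_,
                    ame_a = NA_real_, ame_b = NA_real_,
                    chi_square = NA_real_, tor = NA_real_,
                    mean_length = NA_real_)
  if (need_mcat) {
    cohort <- run_cohort(pool, abilities, assignment,
                         criterion = config$criterion, prior = prior,
                         stopping = config$stopping)
    row$ame_theta <- ame_theta(abilities, cohort$theta_hat)
    row$rmse_theta <- rmse_theta(abilities, cohort$theta_hat)
    row$mean_length <- mean(cohort$test_length)
    if (config$stopping$type == "fixed") {
      es <- exposure_summary(cohort)
      row$chi_square <- exposure_chi_square(es)
      row$tor <- test_overlap_ratio(es)
    }
    config$.replenished <- cohort$replenished
  } else {
    Z1 <- length(assignment$item_groups[[1]])
    U <- matrix(runif(design$N * Z1), design$N, Z1)
    config$.replenished <- .replenished_responses(pool, abilities,
                                                  assignment, U)
  }
  if (config$pattern_step) {
    if (need_mcat) {
      est <- .pattern_indices(pool, assignment, cohort$theta_hat, config)
      row$csr <- est$csr
      row$ame_a <- est$ame_a
      row$ame_b <- est$ame_b
      if (config$theta_source == "both") {
        tru <- .pattern_indices(pool, assignment, abilities, config)
        row$csr_true <- tru$csr
        row$ame_a_true <- tru$ame_a
        row$ame_b_true <- tru$ame_b
      }
    } else {
      tru <- .pattern_indices(pool, assignment, abilities, config)
      row$csr <- tru$csr
      row$ame_a <- tru$ame_a
      row$ame_b <- tru$ame_b
    }
  }
  row
}

#' Run a full simulation study
#'
#' Runs all replications of a configuration serially with isolated
#' per-replication seeds, and averages the per-replication indices. The
#' reported aggregate of every index is the plain mean of the
#' per-replication values.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, writes
#'   `replications.csv`, `aggregate.csv` and a `manifest.txt` recording
#'   the configuration, seeds and package version.
#' @return Object of class `study_report` with `config`, `replications`
#'   (data frame, one row per replication) and `aggregate` (one-row data
#'   frame of means).
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  rows <- lapply(seq_len(config$replications), function(r)
    run_replication(config, r))
  reps <- do.call(rbind, rows)
  idx <- setdiff(names(reps), c("rep", "seed"))
  aggregate <- as.data.frame(as.list(colMeans(reps[, idx, drop = FALSE],
                                              na.rm = TRUE)))
  report <- structure(list(config = config, replications = reps,
                           aggregate = aggregate),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d replications\n", nrow(x$replications)))
  print(x$aggregate, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname run_study
#' @param report a `study_report`.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$replications,
                   file.path(out_dir, "replications.csv"),
                   row.names = FALSE)
  utils::write.csv(report$aggregate, file.path(out_dir, "aggregate.csv"),
                   row.names = FALSE)
  cfg <- report$config
  d <- cfg$design
  lines <- c(
    paste0("package_version: ", as.character(utils::packageVersion("lprm"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("K: ", d$K), paste0("J0: ", d$J0), paste0("J1: ", d$J1),
    paste0("N: ", d$N),
    paste0("disc_range: ", paste(d$disc_range, collapse = ",")),
    paste0("ability_cov_upper: ",
           paste(d$ability_cov[upper.tri(d$ability_cov, diag = TRUE)],
                 collapse = ",")),
    paste0("Z0: ", d$Z0), paste0("Z1: ", d$Z1),
    paste0("n_groups: ", d$n_groups),
    paste0("criterion: ", cfg$criterion),
    paste0("stopping: ", if (cfg$stopping$type == "fixed")
      paste0("fixed:", cfg$stopping$Z0)
      else paste0("variable:", cfg$stopping$se, ":",
                  cfg$stopping$max_items)),
    paste0("grid: ", cfg$grid$T, ":", cfg$grid$W),
    paste0("replications: ", cfg$replications),
    paste0("base_seed: ", cfg$base_seed),
    paste0("seeds: ", paste(report$replications$seed, collapse = ",")),
    paste0("bic_mode: ", cfg$bic_mode),
    paste0("selection_mode: ", cfg$selection_mode),
    paste0("prior_mode: ", cfg$prior_mode),
    paste0("theta_source: ", cfg$theta_source),
    paste0("pattern_step: ", cfg$pattern_step))
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
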