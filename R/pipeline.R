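#' Classify a collection of ensembles into the normality/modality grid
#'
#' Runs the full evidence pipeline per ensemble — optional curation,
#' single-Gaussian and binormal fits, BIC, Bayes posterior, evidence label —
#' and, only for M2 cells, the Helguero modality test. M1 cells are unimodal
#' by definition (`"M1/U"`); IE cells get no modality call. Per-cell failures
#' (too few records, degenerate variance) are recorded in the cell's
#' `status` and never abort the grid.
#'
#' @param ensembles List of [helical_ensemble()] objects.
#' @param config Named list overriding defaults: `k_sd` (3), `filter_origins`
#'   (the X-ray origins), `subsample_m` (NULL), `n_restarts` (4), `seed` (1),
#'   `hi` (0.95), `lo` (0.05), `fit_range` (NULL), `curate` (TRUE).
#' @return A data frame of class `classification_grid`, one row per
#'   ensemble, ordered by the canonical step/parameter/origin ordering, with
#'   columns `step_type`, `parameter`, `origin`, `n`, `bic1`, `bic2`,
#'   `p_m2`, `evidence`, `label`, `separation`, `threshold`, `r`, `s_r`,
#'   `weighted_mean`, `weighted_sd`, `status`, plus component parameters.
#'   Attribute `summary` holds the pooled and per-origin fractions of M2
#'   cells and of B cells among M2.
#' @export
classify_all <- function(ensembles, config = list()) {
  defaults <- list(k_sd = 3, filter_origins = c("xray_naked", "xray_protein",
                                                "xray_intercalator"),
                   subsample_m = NULL, n_restarts = 4L, seed = 1L,
                   hi = 0.95, lo = 0.05, fit_range = NULL, curate = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)
  if (length(ensembles) < 1L) stop("need at least one ensemble")

  if (cfg$curate) {
    cur <- curate_ensembles(ensembles, k_sd = cfg$k_sd,
                            filter_origins = cfg$filter_origins,
                            subsample_m = cfg$subsample_m, seed = cfg$seed)
    ensembles <- cur$ensembles
  }

  rows <- lapply(ensembles, function(e) {
    cell <- data.frame(step_type = e$step_type, parameter = e$parameter,
                       origin = e$origin, n = e$n,
                       bic1 = NA_real_, bic2 = NA_real_, p_m2 = NA_real_,
                       evidence = NA_character_, label = NA_character_,
                       mu1 = NA_real_, sigma1 = NA_real_, mu2 = NA_real_,
                       sigma2 = NA_real_, p_r = NA_real_,
                       separation = NA_real_, threshold = NA_real_,
                       r = NA_real_, s_r = NA_real_,
                       weighted_mean = NA_real_, weighted_sd = NA_real_,
                       status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch({
      ev <- evidence_analysis(e, n_restarts = cfg$n_restarts, seed = cfg$seed,
                              fit_range = cfg$fit_range,
                              hi = cfg$hi, lo = cfg$lo)
      m <- ev$fit2$model
      cell$bic1 <- ev$bic1; cell$bic2 <- ev$bic2; cell$p_m2 <- ev$p_m2
      cell$evidence <- ev$label
      cell$mu1 <- m$mu1; cell$sigma1 <- m$sigma1
      cell$mu2 <- m$mu2; cell$sigma2 <- m$sigma2; cell$p_r <- m$p_r
      if (ev$label == "M1") {
        cell$label <- "M1/U"
      } else if (ev$label == "IE") {
        cell$label <- "IE"
      } else {
        mod <- is_bimodal(m)
        cell$separation <- mod$separation; cell$threshold <- mod$threshold
        cell$r <- mod$r; cell$s_r <- mod$s_r
        cell$label <- paste0("M2/", mod$label)
        ws <- weighted_stats(m)
        cell$weighted_mean <- ws$mean; cell$weighted_sd <- ws$sd
      }
      cell
    }, error = function(err) {
      cell$status <- paste("failed:", conditionMessage(err))
      cell
    })
    res
  })
  grid <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  grid <- grid[order(factor(grid$step_type, levels = HELICAL_STEPS),
                     factor(grid$parameter, levels = HELICAL_PARAMETERS),
                     factor(grid$origin, levels = HELICAL_ORIGINS)), ]
  rownames(grid) <- NULL

  classified <- grid$status == "ok" & !is.na(grid$evidence)
  frac <- function(idx) {
    n_cls <- sum(idx)
    n_m2 <- sum(grid$evidence[idx] == "M2")
    n_b <- sum(grid$label[idx] == "M2/B", na.rm = TRUE)
    c(n_classified = n_cls, fraction_m2 = if (n_cls) n_m2 / n_cls else NA,
      fraction_b_among_m2 = if (n_m2) n_b / n_m2 else NA)
  }
  summ <- list(pooled = frac(classified))
  for (o in unique(grid$origin))
    summ[[o]] <- frac(classified & grid$origin == o)
  attr(grid, "summary") <- summ
  class(grid) <- c("classification_grid", "data.frame")
  grid
}

#' @export
print.classification_grid <- function(x, ...) {
  cat(sprintf("<classification_grid> %d cells\n", nrow(x)))
  print.data.frame(x[, c("step_type", "parameter", "origin", "n", "p_m2",
                         "label", "status")], digits = 4)
  s <- attr(x, "summary")$pooled
  cat(sprintf("pooled: fraction M2 = %.3f, fraction B among M2 = %.3f\n",
              s[["fraction_m2"]], s[["fraction_b_among_m2"]]))
  invisible(x)
}

#' Pairwise helical-parameter correlations per step
#'
#' Pearson correlation matrices of the joint helical parameters, one per
#' (step_type, origin) group — the standard check for known couplings such
#' as the negative twist-roll correlation. Constant columns yield `NA`
#' entries rather than an error.
#'
#' @param joint A data frame with columns `step_type`, `origin` and one
#'   numeric column per helical parameter, one snapshot per row.
#' @return A named list (one entry per group) of correlation matrices.
#' @export
correlation_report <- function(joint) {
  stopifnot(is.data.frame(joint),
            all(c("step_type", "origin") %in% names(joint)))
  num_cols <- setdiff(names(joint), c("step_type", "origin", "context",
                                      "time_ns"))
  key <- interaction(joint$step_type, joint$origin, drop = TRUE, sep = "/")
  lapply(split(joint[num_cols], key), function(df) {
    x <- as.matrix(df)
    sds <- apply(x, 2L, sd)
    cm <- suppressWarnings(cor(x))
    cm[sds == 0, ] <- NA_real_
    cm[, sds == 0] <- NA_real_
    diag(cm)[sds == 0] <- NA_real_
    cm
  })
}

#' Run a full analysis from a config file
#'
#' Deterministic end-to-end driver: reads a flat YAML config, obtains the
#' input ensembles (from files in the `io` section and/or by generating the
#' scenarios of the `simulate` section), classifies them, and writes the
#' report bundle to `out_dir`: the classification grid (TSV), per-cell fit
#' records (JSON), the modality report (TSV), kinetics reports for simulated
#' time series (TSV) and a run log (JSON) with the seed and package version.
#' Running the same config twice produces byte-identical numeric outputs.
#'
#' Config sections (all optional except one of `io` / `simulate`):
#' \describe{
#'   \item{io}{`files`: list of input tables; `dialect`: tsv/csv.}
#'   \item{simulate}{List of scenarios; each has `preset` (see
#'     [scenario_preset()]) or explicit `mu1, sigma1, mu2, sigma2, p_r`,
#'     plus `n` (alias `n_samples`, which avoids the YAML pitfall that an
#'     unquoted `n` key parses as a boolean), and optional `step_type`,
#'     `parameter`, `origin`. A scenario
#'     with `type: telegraph` additionally has `rate_12`, `rate_21`, `dt`,
#'     `duration_ns` and produces a kinetics report.}
#'   \item{curation}{`k_sd`, `filter_origins`, `subsample_m`, `curate`.}
#'   \item{fitting}{`n_restarts`, `fit_range`.}
#'   \item{thresholds}{`hi`, `lo`.}
#'   \item{dynamics}{`windows` (ns), `n_blocks`.}
#'   \item{seed, out_dir}{Global seed and output directory.}
#' }
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @param seed Global seed (overrides the config's `seed`).
#' @return Invisibly, a list with `grid`, `fits`, `kinetics` and the output
#'   paths.
#' @export
run_config <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  known <- c("io", "simulate", "curation", "fitting", "thresholds",
             "dynamics", "energy", "seed", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  seed <- if (!is.null(seed)) seed else if (!is.null(cfg$seed)) cfg$seed else 1L
  out_dir <- if (!is.null(out_dir)) out_dir
             else if (!is.null(cfg$out_dir)) cfg$out_dir else stop("out_dir required")
  if (is.null(cfg$io) && is.null(cfg$simulate))
    stop("config needs an 'io' or 'simulate' section")

  # fail fast on missing inputs before writing anything
  ensembles <- list()
  if (!is.null(cfg$io)) {
    for (f in cfg$io$files)
      if (!file.exists(f)) stop("input file not found: ", f)
    for (f in cfg$io$files)
      ensembles <- c(ensembles,
                     read_helical_table(f, dialect = cfg$io$dialect %||% "tsv"))
  }

  kinetics <- list()
  if (!is.null(cfg$simulate)) {
    for (i in seq_along(cfg$simulate)) {
      sc <- cfg$simulate[[i]]
      # YAML 1.1 parses an unquoted `n:` key as boolean FALSE; map it back,
      # and accept `n_samples` as an unambiguous alias
      names(sc)[names(sc) == "FALSE"] <- "n"
      if (is.null(sc$n) && !is.null(sc$n_samples)) sc$n <- sc$n_samples
      sc_seed <- seed + i
      if (identical(sc$type, "telegraph")) {
        em <- binormal_spec(sc$mu1, sc$sigma1, sc$mu2, sc$sigma2,
                            sc$p_r %||% 0.5)
        ts <- telegraph_spec(sc$rate_12, sc$rate_21, em, sc$dt)
        sim <- sample_telegraph(ts, sc$duration_ns, seed = sc_seed,
                                step_type = sc$step_type %||% "CG",
                                parameter = sc$parameter %||% "twist",
                                origin = sc$origin %||% "md")
        ensembles <- c(ensembles, list(sim$series))
        kinetics[[length(kinetics) + 1L]] <-
          list(series = sim$series, name = sc$name %||% paste0("telegraph_", i))
      } else {
        spec <- if (!is.null(sc$preset)) scenario_preset(sc$preset)
                else list(spec = binormal_spec(sc$mu1, sc$sigma1, sc$mu2,
                                               sc$sigma2, sc$p_r),
                          step_type = sc$step_type %||% "CG",
                          parameter = sc$parameter %||% "twist",
                          origin = sc$origin %||% "md")
        ensembles <- c(ensembles,
                       list(sample_binormal(spec$spec, sc$n, seed = sc_seed,
                                            step_type = sc$step_type %||% spec$step_type,
                                            parameter = sc$parameter %||% spec$parameter,
                                            origin = sc$origin %||% spec$origin)))
      }
    }
  }

  ccfg <- c(cfg$curation %||% list(), cfg$fitting %||% list(),
            cfg$thresholds %||% list())
  ccfg$seed <- seed
  grid <- classify_all(ensembles, ccfg)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(grid = file.path(out_dir, "classification_grid.tsv"),
                fits = file.path(out_dir, "fits.json"),
                modality = file.path(out_dir, "modality.tsv"),
                log = file.path(out_dir, "run_log.json"))
  write_grid_tsv(grid, paths$grid)
  jsonlite::write_json(grid_to_fit_records(grid), paths$fits,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mod <- grid[!is.na(grid$separation),
              c("step_type", "parameter", "origin", "label", "r", "s_r",
                "separation", "threshold", "weighted_mean", "weighted_sd")]
  write_report_tsv(mod, paths$modality)

  kin_out <- list()
  if (length(kinetics) > 0L) {
    windows <- cfg$dynamics$windows
    for (k in kinetics) {
      fit <- fit_binormal(k$series, seed = seed)
      w <- if (!is.null(windows)) windows
           else diff(range(k$series$time))
      prof <- convergence_profile(k$series, fit, w,
                                  n_blocks = cfg$dynamics$n_blocks %||% 10L)
      p <- file.path(out_dir, paste0("kinetics_", k$name, ".tsv"))
      write_report_tsv(prof, p)
      kin_out[[k$name]] <- prof
      paths[[paste0("kinetics_", k$name)]] <- p
    }
  }

  jsonlite::write_json(
    list(package = "helibimod",
         version = as.character(utils::packageVersion("helibimod")),
         seed = seed, n_ensembles = length(ensembles),
         summary = attr(grid, "summary")),
    paths$log, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(grid = grid, kinetics = kin_out, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all numeric report columns at 6 significant digits (diff-stable output)
write_report_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_grid_tsv <- function(grid, path) {
  write_report_tsv(as.data.frame(grid), path)
}

grid_to_fit_records <- function(grid) {
  lapply(seq_len(nrow(grid)), function(i) {
    r <- grid[i, ]
    list(step_type = r$step_type, parameter = r$parameter, origin = r$origin,
         n = r$n, bic1 = r$bic1, bic2 = r$bic2, p_m2 = r$p_m2,
         evidence = r$evidence, label = r$label,
         binormal = list(mu1 = r$mu1, sigma1 = r$sigma1, mu2 = r$mu2,
                         sigma2 = r$sigma2, p_r = r$p_r),
         status = r$status)
  })
}
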