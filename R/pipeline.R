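# End-to-end workflow: load or generate a study, screen and clean the
# schools, fit each retained school, pool across schools, and render
# report tables.

#' Study run configuration
#'
#' @param mode `"synthetic"` (generate panels from `synthetic`) or
#'   `"real_data"` (read panels from `schools`).
#' @param synthetic a [synthetic_config()] (synthetic mode).
#' @param schools real-data mode: list of per-school lists with fields
#'   `wave1`, `wave2`, `covariates` (file paths), optional `schema` and
#'   `school_id`, passed to [read_panel()].
#' @param model the `saom_model` effect specification to fit; defaults
#'   to the full 19-effect network selection and 8-effect behavior
#'   evolution sets.
#' @param control a [saom_control()]; use `saom_control(scaled = TRUE)`
#'   for quick runs.
#' @param jaccard_threshold school screening threshold (default 0.20).
#' @param seed master seed of the run; all per-school fitting seeds
#'   derive from it.
#' @param out_degree_cap optional nomination cap enforced in fitting
#'   simulations.
#' @return a list of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "real_data"),
                         synthetic = synthetic_config(),
                         schools = NULL,
                         model = NULL,
                         control = saom_control(),
                         jaccard_threshold = 0.20,
                         seed = 1L,
                         out_degree_cap = NULL) {
  mode <- match.arg(mode)
  if (mode == "real_data" && is.null(schools))
    stop("real_data mode requires school file paths")
  model <- model %||% saom_model(network_selection_effects(),
                                 behavior_evolution_effects())
  structure(list(mode = mode, synthetic = synthetic, schools = schools,
                 model = model, control = control,
                 jaccard_threshold = jaccard_threshold,
                 seed = as.integer(seed), out_degree_cap = out_degree_cap),
            class = "study_config")
}

load_study_panels <- function(config) {
  if (config$mode == "synthetic") {
    study <- generate_study(config$synthetic)
    list(panels = study$panels, manifest = study$manifest)
  } else {
    panels <- lapply(seq_along(config$schools), function(k) {
      sch <- config$schools[[k]]
      do.call(read_panel, c(
        list(wave1_file = sch$wave1, wave2_file = sch$wave2,
             covariate_file = sch$covariates),
        if (!is.null(sch$schema)) list(schema = sch$schema),
        if (!is.null(sch$school_id)) list(school_id = sch$school_id)))
    })
    list(panels = panels,
         manifest = list(n_schools = length(panels),
                         school_ids = vapply(panels, `[[`, "", "school_id"),
                         source = "files"))
  }
}

#' Run the full multi-school analysis
#'
#' Pipeline order: load (or generate) each school; drop actors with no
#' ties at either wave; carry wave-1 data forward for wave-2
#' non-responders; screen schools on the Jaccard stability index
#' (excluded schools are logged with their index value); fit the
#' co-evolution model to each retained school by Method of Moments;
#' pool every effect across schools with the Snijders-Baerveldt test
#' and both one-sided Fisher combinations; convert similarity-effect
#' estimates to odds ratios.  Non-converged schools are reported and
#' excluded from the meta-analysis with a warning.  Identical
#' configuration and seed give identical results.
#'
#' @param config a [study_config()].
#' @return an object of class `saom_study`: per-school `fits`, meta
#'   tables `meta_network` and `meta_behavior`, `odds_ratios` for
#'   similarity effects, the exclusion log `excluded`, `descriptives`,
#'   `attrition`, the data `manifest`, and the `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  loaded <- load_study_panels(config)
  panels <- loaded$panels

  cleaned <- list()
  excluded <- data.frame(school_id = character(), jaccard = numeric(),
                         reason = character())
  for (p in panels) {
    res <- tryCatch({
      q <- impute_locf(filter_isolates(p))
      j <- jaccard_index(q)
      if (j < config$jaccard_threshold) {
        message(sprintf("[screen] school %s excluded: Jaccard %.3f < %.2f",
                        q$school_id, j, config$jaccard_threshold))
        excluded <- rbind(excluded,
                          data.frame(school_id = q$school_id, jaccard = j,
                                     reason = "low Jaccard stability"))
        NULL
      } else q
    }, error = function(e) {
      excluded <<- rbind(excluded,
                         data.frame(school_id = p$school_id,
                                    jaccard = NA_real_,
                                    reason = conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) cleaned[[length(cleaned) + 1L]] <- res
  }
  if (!length(cleaned))
    stop("no schools retained after screening (",
         nrow(excluded), " excluded)")

  fits <- lapply(seq_along(cleaned), function(k) {
    q <- cleaned[[k]]
    message(sprintf("[fit] school %s (n = %d)", q$school_id, q$n))
    fit_school(q, config$model, control = config$control,
               seed = derive_seed(config$seed, 5000L + k),
               out_degree_cap = config$out_degree_cap)
  })

  conv <- vapply(fits, `[[`, logical(1), "converged")
  meta_network <- meta_behavior <- NULL
  if (sum(conv) >= 2) {
    meta_network <- meta_analyze(fits, side = "network")
    if (length(config$model$behavior_effects))
      meta_behavior <- meta_analyze(fits, side = "behavior")
  } else {
    warning("fewer than 2 converged schools; meta-analysis skipped")
  }

  odds <- NULL
  if (!is.null(meta_network)) {
    sim_rows <- grep("_similarity$", meta_network$effect)
    if (length(sim_rows)) {
      odds <- do.call(rbind, lapply(sim_rows, function(r) {
        o <- selection_odds_ratio(meta_network$mu_hat[r],
                                  meta_network$se_mu[r])
        data.frame(effect = meta_network$effect[r],
                   odds_ratio = o$odds_ratio_2dp,
                   ci_low = o$ci[1], ci_high = o$ci[2],
                   ci_type = o$ci_type)
      }))
    }
  }

  structure(
    list(fits = fits, meta_network = meta_network,
         meta_behavior = meta_behavior, odds_ratios = odds,
         excluded = excluded,
         descriptives = descriptive_table(cleaned),
         attrition = attrition_summary(cleaned),
         manifest = c(loaded$manifest,
                      list(run_seed = config$seed,
                           jaccard_threshold = config$jaccard_threshold)),
         config = config),
    class = "saom_study"
  )
}

#' @export
print.saom_study <- function(x, ...) {
  cat("Multi-school co-evolution analysis: ", length(x$fits),
      " fitted school(s), ", nrow(x$excluded), " excluded\n", sep = "")
  cat(sprintf("  pooled retention: %.1f%%\n", x$attrition$retention_pct))
  if (!is.null(x$meta_network)) {
    cat("\nNetwork selection effects:\n")
    print(x$meta_network)
  }
  if (!is.null(x$meta_behavior)) {
    cat("\nBehavior evolution effects:\n")
    print(x$meta_behavior)
  }
  invisible(x)
}

#' Per-school descriptive statistics
#'
#' Mirrors the usual network descriptive table: per school and wave,
#' the actor count, mean out-going nominations, percentage of
#' reciprocated ties (mutual-dyad ties over all ties), the Jaccard
#' stability index, and the behavior distribution with the top two
#' levels collapsed to "weekly or more often".
#'
#' @param panels list of `school_panel`s.
#' @return a data frame, one row per school.
#' @export
descriptive_table <- function(panels) {
  if (inherits(panels, "school_panel")) panels <- list(panels)
  recip_pct <- function(x) {
    ties <- sum(x)
    if (ties == 0) return(NA_real_)
    100 * sum(x * t(x)) / ties
  }
  beh_dist <- function(z, L) {
    pr <- tabulate(z, nbins = L) / length(z)
    c(pr[seq_len(L - 2)], sum(pr[c(L - 1, L)]))
  }
  do.call(rbind, lapply(panels, function(p) {
    x2 <- ifelse(is.na(p$x2), 0, p$x2)
    b1 <- beh_dist(p$z1, p$n_levels)
    b2 <- beh_dist(p$z2, p$n_levels)
    cbind(
      data.frame(
        school_id = p$school_id, n = p$n,
        mean_nominations_w1 = mean(rowSums(p$x1)),
        mean_nominations_w2 = mean(rowSums(x2)),
        reciprocal_pct_w1 = recip_pct(p$x1),
        reciprocal_pct_w2 = recip_pct(x2),
        jaccard = tryCatch(jaccard_index(p), error = function(e) NA_real_)
      ),
      stats::setNames(as.data.frame(t(b1)),
                      paste0("beh", seq_along(b1), "_w1")),
      stats::setNames(as.data.frame(t(b2)),
                      paste0("beh", seq_along(b2), "_w2"))
    )
  }))
}

# Fixed-precision number formatting shared by both report renderings so
# they carry identical values.
fmt_num <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 6, format = "g") else as.character(x)
}

md_table <- function(df) {
  cells <- sapply(df, function(col) vapply(col, fmt_num, ""))
  cells <- matrix(as.character(cells), nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, body)
}

#' Write report files for a study
#'
#' Emits the meta tables (effect, beta, SE, p, between-school SD,
#' Fisher right/left, verdict), the per-school fit table, the
#' descriptive table, the attrition summary, the exclusion log and the
#' data manifest, as tab-delimited text and/or markdown.  Both formats
#' carry identical numbers, and re-running with the same study object
#' reproduces the files byte for byte.
#'
#' @param study a `saom_study` from [run_study()].
#' @param dir output directory (created if needed).
#' @param format `"delimited"`, `"markdown"`, or both.
#' @return invisibly, the paths written.
#' @export
render_reports <- function(study, dir,
                           format = c("delimited", "markdown")) {
  stopifnot(inherits(study, "saom_study"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  meta_df <- function(m) {
    data.frame(effect = m$effect, beta = m$mu_hat, se = m$se_mu,
               p = m$p_two_sided, between_school_sd = m$sigma_between,
               fisher_right = m$fisher_right_p,
               fisher_left = m$fisher_left_p,
               significant = m$significant, note = m$note)
  }
  tables <- list(
    network_meta = if (!is.null(study$meta_network))
      meta_df(study$meta_network),
    behavior_meta = if (!is.null(study$meta_behavior))
      meta_df(study$meta_behavior),
    school_fits = do.call(rbind, lapply(study$fits, function(f) {
      s <- summary(f)
      data.frame(school_id = f$school_id, n = f$n_actors,
                 effect = s$parameter, beta = s$estimate, se = s$se,
                 t_conv = s$t_conv, converged = f$converged,
                 seed = f$seed)
    })),
    odds_ratios = study$odds_ratios,
    descriptives = study$descriptives,
    excluded = if (nrow(study$excluded)) study$excluded,
    attrition = data.frame(n_wave1 = study$attrition$n_wave1,
                           n_wave2 = study$attrition$n_wave2,
                           retention_pct = study$attrition$retention_pct)
  )
  if (is.null(tables$behavior_meta) &&
      !length(study$config$model$behavior_effects))
    message("[report] behavior side empty in configuration; ",
            "behavior table omitted")
  for (nm in names(tables)) {
    df <- tables[[nm]]
    if (is.null(df)) next
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) fmt_num(col) else col)
    if ("delimited" %in% format) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(df, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, f)
    }
    if ("markdown" %in% format) {
      f <- file.path(dir, paste0(nm, ".md"))
      writeLines(md_table(df), f)
      paths <- c(paths, f)
    }
  }
  mf <- file.path(dir, "manifest.txt")
  man <- study$manifest
  lines <- unlist(lapply(names(man), function(k) {
    v <- man[[k]]
    if (is.list(v))
      vapply(seq_along(v), function(j)
        paste0(k, ".", j, " = ",
               paste(fmt_num(unlist(v[[j]])), collapse = ",")), "")
    else paste0(k, " = ", paste(fmt_num(v), collapse = ","))
  }))
  writeLines(lines, mf)
  paths <- c(paths, mf)
  invisible(paths)
}

#' Box-summary plot of per-school coefficients
#'
#' One box per effect summarising the spread of the per-school
#' estimates (the cross-school analogue of a coefficient forest),
#' with pooled-significant effects marked by an asterisk.
#'
#' @param x a `saom_study`.
#' @param side `"network"` or `"behavior"` effects.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the matrix of per-school coefficients plotted.
#' @export
plot.saom_study <- function(x, side = c("network", "behavior"), ...) {
  side <- match.arg(side)
  meta <- if (side == "network") x$meta_network else x$meta_behavior
  if (is.null(meta)) stop("no meta-analysis available for this side")
  fits <- Filter(function(f) f$converged, x$fits)
  co <- sapply(fits, function(f) f$theta[meta$effect])
  co <- matrix(co, nrow = nrow(meta),
               dimnames = list(meta$effect, NULL))
  labels <- paste0(meta$effect, ifelse(meta$significant, " *", ""))
  graphics::boxplot(t(co), names = labels, las = 2, cex.axis = 0.7,
                    ylab = "per-school coefficient", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(co)
}
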