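#' Two-wave school network panel
#'
#' A `school_panel` holds one school's data for the co-evolution
#' analysis: a directed friendship network observed at two waves, an
#' ordinal behavior score (alcohol-use frequency on a 6-point scale:
#' never / 1-2 times / 3-12 times / monthly but not weekly / weekly /
#' more than once a week) for each actor at each wave, actor covariates,
#' and wave-2 response indicators.  Wave-2 rows (outgoing ties) and
#' behavior values of non-responders may be `NA` until
#' [impute_locf()] carries wave 1 forward and flags the filled cells.
#'
#' @param school_id character scalar identifying the school.
#' @param wave1,wave2 square 0/1 adjacency matrices (rows = nominating
#'   actor, columns = nominated actor) with identical dimnames giving
#'   actor identifiers.  `wave2` rows of non-responders may be `NA`.
#' @param behavior1,behavior2 integer vectors of behavior levels in
#'   `1..n_levels`; `behavior2` may be `NA` for non-responders.
#' @param covariates data frame of actor covariates, one row per actor
#'   in the same order as the adjacency dimnames.
#' @param responded_wave2 logical vector; `FALSE` marks wave-2
#'   non-responders.  Defaults to all `TRUE`.
#' @param n_levels number of behavior categories (6 for the alcohol
#'   frequency scale).
#' @return an object of class `school_panel`.
#' @seealso [read_panel()], [filter_isolates()], [impute_locf()],
#'   [jaccard_index()]
#' @export
school_panel <- function(school_id, wave1, wave2, behavior1, behavior2,
                         covariates = NULL, responded_wave2 = NULL,
                         n_levels = 6L) {
  wave1 <- as.matrix(wave1)
  wave2 <- as.matrix(wave2)
  n <- nrow(wave1)
  actors <- rownames(wave1) %||% as.character(seq_len(n))
  dimnames(wave1) <- dimnames(wave2) <- list(actors, actors)
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = actors)
  } else {
    covariates <- as.data.frame(covariates)
    rownames(covariates) <- actors
  }
  responded_wave2 <- responded_wave2 %||% rep(TRUE, n)
  p <- structure(
    list(
      school_id = as.character(school_id),
      actors = actors,
      n = n,
      x1 = wave1,
      x2 = wave2,
      z1 = as.integer(behavior1),
      z2 = as.integer(behavior2),
      covariates = covariates,
      responded_wave2 = as.logical(responded_wave2),
      imputed_ties = matrix(FALSE, n, n, dimnames = list(actors, actors)),
      imputed_behavior = rep(FALSE, n),
      n_levels = as.integer(n_levels)
    ),
    class = "school_panel"
  )
  validate_school_panel(p)
}

#' Validate a school panel
#'
#' Checks the structural invariants: square conformable tie matrices
#' with an empty diagonal, binary tie values, behavior levels within
#' the declared range, and imputation flags confined to rows of wave-2
#' non-responders.
#'
#' @param p a `school_panel`.
#' @return `p`, invisibly usable, after validation; errors otherwise.
#' @export
validate_school_panel <- function(p) {
  stopifnot(inherits(p, "school_panel"))
  n <- p$n
  if (nrow(p$x1) != n || ncol(p$x1) != n || nrow(p$x2) != n || ncol(p$x2) != n)
    stop("tie matrices must be ", n, " x ", n)
  for (w in c("x1", "x2")) {
    x <- p[[w]]
    d <- diag(x)
    if (any(d != 0, na.rm = TRUE))
      stop("self-ties are not allowed (", w, ")")
    v <- x[!is.na(x)]
    if (any(v != 0 & v != 1)) stop("tie values must be 0/1 (", w, ")")
  }
  if (anyNA(p$z1)) stop("wave-1 behavior must be fully observed")
  zz <- c(p$z1, p$z2[!is.na(p$z2)])
  if (any(zz < 1L | zz > p$n_levels))
    stop("behavior levels must lie in 1..", p$n_levels)
  if (length(p$responded_wave2) != n)
    stop("responded_wave2 must have one entry per actor")
  # NA wave-2 cells and imputation flags only for non-responders
  na_rows <- apply(is.na(p$x2), 1L, any)
  if (any(na_rows & p$responded_wave2))
    stop("NA wave-2 ties found for responders")
  if (any(rowSums(p$imputed_ties) > 0 & p$responded_wave2))
    stop("imputation flags set for responders")
  if (!is.null(p$covariates) && nrow(p$covariates) != n)
    stop("covariate table must have one row per actor")
  p
}

#' @export
print.school_panel <- function(x, ...) {
  cat("School panel '", x$school_id, "': ", x$n, " actors\n", sep = "")
  cat("  wave-1 ties: ", sum(x$x1), ", wave-2 ties: ",
      sum(x$x2, na.rm = TRUE), "\n", sep = "")
  cat("  wave-2 responders: ", sum(x$responded_wave2), "/", x$n, "\n",
      sep = "")
  jc <- tryCatch(jaccard_counts(x), error = function(e) NULL)
  if (!is.null(jc) && (jc$f11 + jc$f01 + jc$f10) > 0)
    cat("  Jaccard stability: ",
        formatC(jaccard_index(jc), digits = 3, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Tie-change counts between waves
#'
#' Counts, over observed cells only (rows of wave-2 responders; cells
#' filled by carry-forward are non-informative and excluded), the ties
#' present at both waves (`f11`), newly formed at wave 2 (`f01`), and
#' dissolved after wave 1 (`f10`).
#'
#' @param p a `school_panel`.
#' @return a list with integer components `f11`, `f01`, `f10`.
#' @export
jaccard_counts <- function(p) {
  stopifnot(inherits(p, "school_panel"))
  keep <- p$responded_wave2
  x1 <- p$x1[keep, , drop = FALSE]
  x2 <- p$x2[keep, , drop = FALSE]
  obs <- !is.na(x2) & !p$imputed_ties[keep, , drop = FALSE]
  diag_idx <- cbind(seq_len(sum(keep)), which(keep))
  obs[diag_idx] <- FALSE
  list(
    f11 = sum(x1 == 1 & x2 == 1 & obs, na.rm = TRUE),
    f01 = sum(x1 == 0 & x2 == 1 & obs, na.rm = TRUE),
    f10 = sum(x1 == 1 & x2 == 0 & obs, na.rm = TRUE)
  )
}

#' Jaccard index of network stability between waves
#'
#' The Jaccard index J = F11 / (F11 + F01 + F10) measures the fraction
#' of friendship ties reported at either wave that persist across both,
#' where F11 counts ties present at both waves, F01 ties newly formed
#' and F10 ties dissolved.  Low values signal unstable panel data that
#' give actor-based estimation little to work with.
#'
#' @param x either a list with components `f11`, `f01`, `f10` (as
#'   returned by [jaccard_counts()]) or a `school_panel`.
#' @return the index, a number in `[0, 1]`.
#' @examples
#' jaccard_index(list(f11 = 2, f01 = 1, f10 = 1))  # 0.5
#' @export
jaccard_index <- function(x) {
  if (inherits(x, "school_panel")) x <- jaccard_counts(x)
  stopifnot(all(c("f11", "f01", "f10") %in% names(x)))
  f11 <- x$f11; f01 <- x$f01; f10 <- x$f10
  if (any(c(f11, f01, f10) < 0)) stop("Jaccard counts must be non-negative")
  tot <- f11 + f01 + f10
  if (tot == 0)
    stop("Jaccard index undefined: no ties at either wave")
  f11 / tot
}

#' Screen a school on between-wave network stability
#'
#' A school is retained for actor-based analysis when its Jaccard
#' stability index is at or above `threshold` (default 0.20, the usual
#' admission bar for two-wave actor-oriented modelling).  The counts
#' are computed over observed cells only.
#'
#' @param p a `school_panel`.
#' @param threshold minimum admissible Jaccard index.
#' @return `TRUE` to retain, `FALSE` to exclude.
#' @export
screen_school <- function(p, threshold = 0.20) {
  jaccard_index(p) >= threshold
}

#' Drop actors with no ties at either wave
#'
#' Removes actors who neither named nor were named by at least one
#' friend at wave 1 or wave 2; such isolates carry no network
#' information.  An actor with a single incoming or outgoing tie at
#' either wave is retained.  Idempotent.
#'
#' @param p a `school_panel`.
#' @return the filtered `school_panel`, consistently re-indexed.
#' @export
filter_isolates <- function(p) {
  stopifnot(inherits(p, "school_panel"))
  x1 <- p$x1
  x2 <- ifelse(is.na(p$x2), 0, p$x2)
  deg <- rowSums(x1) + colSums(x1) + rowSums(x2) + colSums(x2)
  keep <- deg > 0
  if (sum(keep) < 2)
    stop("degenerate school: fewer than 2 non-isolated actors")
  if (all(keep)) return(p)
  p$actors <- p$actors[keep]
  p$n <- sum(keep)
  p$x1 <- p$x1[keep, keep, drop = FALSE]
  p$x2 <- p$x2[keep, keep, drop = FALSE]
  p$z1 <- p$z1[keep]
  p$z2 <- p$z2[keep]
  p$covariates <- p$covariates[keep, , drop = FALSE]
  p$responded_wave2 <- p$responded_wave2[keep]
  p$imputed_ties <- p$imputed_ties[keep, keep, drop = FALSE]
  p$imputed_behavior <- p$imputed_behavior[keep]
  validate_school_panel(p)
}

#' Carry wave-1 data forward for wave-2 non-responders
#'
#' Applies last-observation-carry-forward imputation: each
#' non-responder's wave-2 outgoing tie row is replaced by their wave-1
#' row and flagged non-informative, and their wave-2 behavior is set to
#' the wave-1 level and flagged.  Incoming ties to non-responders, as
#' reported by responders, are left untouched and remain informative.
#' Wave-1 data are never altered.
#'
#' @param p a `school_panel` with `responded_wave2` flags set.
#' @return the imputed `school_panel` with `imputed_ties` and
#'   `imputed_behavior` marking every filled cell.
#' @export
impute_locf <- function(p) {
  stopifnot(inherits(p, "school_panel"))
  nr <- which(!p$responded_wave2)
  for (i in nr) {
    p$x2[i, ] <- p$x1[i, ]
    p$imputed_ties[i, ] <- TRUE
    p$imputed_ties[i, i] <- FALSE
    p$z2[i] <- p$z1[i]
    p$imputed_behavior[i] <- TRUE
  }
  validate_school_panel(p)
}

#' Retention percentage with floor-at-one-decimal reporting
#'
#' @param n1,n2 wave-1 and wave-2 head counts.
#' @return `floor(1000 * n2 / n1) / 10`, the retention percentage
#'   truncated (not rounded) at one decimal place.
#' @export
retention_percent <- function(n1, n2) {
  if (n1 <= 0) stop("wave-1 count must be positive")
  floor(1000 * n2 / n1) / 10
}

#' Summarise wave-2 attrition
#'
#' Reports wave-1 and wave-2 head counts, the retention percentage
#' (truncated at one decimal place), and the wave-1 behavior
#' distribution split by wave-2 responder status — the comparison used
#' to show that heavier drinkers are lost at a higher rate.
#'
#' @param x a `school_panel`, a list of them (pooled), or a numeric
#'   vector `c(n1, n2)` of raw head counts.
#' @return a list with components `n_wave1`, `n_wave2`,
#'   `retention_pct`, and (when behavior data are available)
#'   `behavior_by_response`, a proportion table of wave-1 behavior
#'   level by responder status.
#' @examples
#' attrition_summary(c(2563, 2299))$retention_pct  # 89.6
#' @export
attrition_summary <- function(x) {
  if (is.numeric(x) && length(x) == 2L) {
    return(list(n_wave1 = x[[1]], n_wave2 = x[[2]],
                retention_pct = retention_percent(x[[1]], x[[2]])))
  }
  panels <- if (inherits(x, "school_panel")) list(x) else x
  stopifnot(all(vapply(panels, inherits, logical(1), "school_panel")))
  resp <- unlist(lapply(panels, `[[`, "responded_wave2"))
  z1 <- unlist(lapply(panels, `[[`, "z1"))
  n1 <- length(resp)
  n2 <- sum(resp)
  tab <- prop.table(table(
    responded = factor(resp, levels = c(FALSE, TRUE),
                       labels = c("lost", "retained")),
    behavior_wave1 = factor(z1, levels = seq_len(panels[[1]]$n_levels))
  ), margin = 1L)
  list(n_wave1 = n1, n_wave2 = n2,
       retention_pct = retention_percent(n1, n2),
       behavior_by_response = tab)
}

# ---------------------------------------------------------------------------
# File I/O: delimited edge lists + covariate table

#' Read a two-wave school panel from delimited text files
#'
#' Edge files are header-bearing delimited text with source and target
#' identifier columns, one file per wave.  The covariate file has one
#' row per actor and supplies the behavior levels for both waves; its
#' actor identifier column keys the edges.  Actors present in the
#' covariate file but in no edge file are retained as isolates (and can
#' be dropped later with [filter_isolates()]).  Duplicate edge rows
#' collapse to a single tie.
#'
#' @param wave1_file,wave2_file paths to the per-wave edge lists.
#' @param covariate_file path to the actor table.
#' @param schema named list mapping roles to column names; recognised
#'   roles: `source`, `target`, `id`, `behavior_wave1`,
#'   `behavior_wave2`, `responded_wave2`, and any covariate columns via
#'   `covariates` (character vector of column names to carry along).
#' @param school_id identifier for the school; defaults to the
#'   covariate file name.
#' @param sep field separator (default tab).
#' @param n_levels number of behavior categories.
#' @return a validated `school_panel`.
#' @export
read_panel <- function(wave1_file, wave2_file, covariate_file,
                       schema = list(), school_id = NULL, sep = "\t",
                       n_levels = 6L) {
  schema <- utils::modifyList(
    list(source = "source", target = "target", id = "id",
         behavior_wave1 = "behavior_wave1", behavior_wave2 = "behavior_wave2",
         responded_wave2 = "responded_wave2", covariates = NULL),
    schema)
  cov <- utils::read.table(covariate_file, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = stats::setNames("character",
                                                        schema$id))
  if (!schema$id %in% names(cov))
    stop("covariate file lacks identifier column '", schema$id, "'")
  actors <- as.character(cov[[schema$id]])
  if (anyDuplicated(actors)) stop("duplicate actor identifiers in covariates")
  n <- length(actors)

  read_edges <- function(f) {
    e <- utils::read.table(f, header = TRUE, sep = sep,
                           colClasses = "character")
    for (col in c(schema$source, schema$target)) {
      if (!col %in% names(e)) stop("edge file ", f, " lacks column '", col, "'")
      bad <- !e[[col]] %in% actors
      if (any(bad))
        stop("unknown actor identifier '", e[[col]][which(bad)[1]],
             "' in edge file ", f, " (row ", which(bad)[1], ")")
    }
    x <- matrix(0, n, n, dimnames = list(actors, actors))
    if (nrow(e)) {
      idx <- cbind(match(e[[schema$source]], actors),
                   match(e[[schema$target]], actors))
      idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]  # ignore self-loops
      x[idx] <- 1  # duplicates collapse
    }
    x
  }
  x1 <- read_edges(wave1_file)
  x2 <- read_edges(wave2_file)

  get_beh <- function(col) {
    if (!col %in% names(cov)) stop("covariate file lacks column '", col, "'")
    z <- suppressWarnings(as.numeric(cov[[col]]))
    ok <- is.na(z) | (z == round(z) & z >= 1 & z <= n_levels)
    if (!all(ok))
      stop("behavior value outside 1..", n_levels, " for actor '",
           actors[which(!ok)[1]], "'")
    as.integer(z)
  }
  z1 <- get_beh(schema$behavior_wave1)
  z2 <- get_beh(schema$behavior_wave2)
  resp <- if (schema$responded_wave2 %in% names(cov)) {
    as.logical(as.integer(cov[[schema$responded_wave2]]))
  } else rep(TRUE, n)
  if (anyNA(z1)) stop("wave-1 behavior must be observed for all actors")
  z2[!resp] <- NA_integer_
  x2[!resp, ] <- NA_real_
  diag(x2) <- 0

  keep_cols <- schema$covariates %||%
    setdiff(names(cov), c(schema$id, schema$behavior_wave1,
                          schema$behavior_wave2, schema$responded_wave2))
  covtab <- cov[, keep_cols, drop = FALSE]
  for (cn in names(covtab)) {
    num <- suppressWarnings(as.numeric(covtab[[cn]]))
    if (!anyNA(num)) covtab[[cn]] <- num
  }
  rownames(covtab) <- actors

  school_panel(school_id %||% basename(covariate_file),
               x1, x2, z1, z2, covtab, resp, n_levels = n_levels)
}

#' Write a school panel to delimited text files
#'
#' Emits the formats [read_panel()] consumes: one edge list per wave
#' and one covariate table carrying behavior levels and response flags.
#'
#' @param p a `school_panel`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; defaults to the school id.
#' @param sep field separator.
#' @return invisibly, the three file paths written.
#' @export
write_panel <- function(p, dir, prefix = p$school_id, sep = "\t") {
  stopifnot(inherits(p, "school_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_wave1.tsv", "_wave2.tsv",
                                           "_actors.tsv")))
  edge_df <- function(x) {
    idx <- which(!is.na(x) & x == 1, arr.ind = TRUE)
    data.frame(source = p$actors[idx[, 1]], target = p$actors[idx[, 2]])
  }
  for (k in 1:2) {
    e <- edge_df(if (k == 1) p$x1 else p$x2)
    e <- e[order(e$source, e$target), , drop = FALSE]
    utils::write.table(e, paths[k], sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  ct <- cbind(data.frame(id = p$actors), p$covariates,
              data.frame(behavior_wave1 = p$z1, behavior_wave2 = p$z2,
                         responded_wave2 = as.integer(p$responded_wave2)))
  utils::write.table(ct, paths[3], sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Export one wave of a panel as a Pajek network file
#'
#' @param p a `school_panel`.
#' @param file output path (`.net`).
#' @param wave which wave to export (1 or 2).
#' @return invisibly, `file`.
#' @export
write_pajek <- function(p, file, wave = 1L) {
  stopifnot(inherits(p, "school_panel"))
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("Pajek export requires the 'igraph' package")
  x <- if (wave == 1L) p$x1 else ifelse(is.na(p$x2), 0, p$x2)
  g <- igraph::graph_from_adjacency_matrix(x, mode = "directed")
  igraph::write_graph(g, file, format = "pajek")
  invisible(file)
}
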