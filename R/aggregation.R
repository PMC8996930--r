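#' Experimental design description
#'
#' The reference design: two rearing-air temperatures (comfort 23 C, heat
#' stress 31 C) crossed with environmental enrichment (enriched vs
#' nonenriched), seven hours of video per condition sampled at 1 frame/s
#' and averaged in 14 blocks of 30 min (1800 frames per block, 25,200
#' frames per condition). All fields are configurable so that scaled-down
#' sessions can reuse the same machinery.
#'
#' @param temperature_levels named numeric vector of air temperatures (C).
#' @param enrichment_levels character vector of enrichment levels.
#' @param block_duration_min duration of one averaging block, minutes.
#' @param session_hours recording session length, hours; must divide evenly
#'   into blocks.
#' @param sample_rate_fps sampling rate, frames per second.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(temperature_levels = c(comfort = 23,
                                                     heat_stress = 31),
                              enrichment_levels = c("enriched",
                                                    "nonenriched"),
                              block_duration_min = 30,
                              session_hours = 7,
                              sample_rate_fps = 1) {
  if (length(temperature_levels) < 1L || length(enrichment_levels) < 1L)
    stop_input("factor levels must be non-empty")
  nb <- session_hours * 60 / block_duration_min
  if (abs(nb - round(nb)) > 1e-9)
    stop_input("session_hours must divide evenly into blocks of ",
               block_duration_min, " min")
  structure(list(temperature_levels = temperature_levels,
                 enrichment_levels = enrichment_levels,
                 block_duration_min = block_duration_min,
                 session_hours = session_hours,
                 sample_rate_fps = sample_rate_fps),
            class = "experiment_design")
}

#' Design bookkeeping: frames and blocks per session
#'
#' `frames_per_session()` is `session_hours * 3600 * sample_rate_fps`;
#' `n_blocks()` is `session_hours * 60 / block_duration_min`;
#' `frames_per_block()` is `block_duration_min * 60 * sample_rate_fps`.
#' With the default design these are 25,200, 14 and 1800.
#'
#' @param design an [experiment_design] object.
#' @return Integer count.
#' @export
frames_per_session <- function(design) {
  as.integer(round(design$session_hours * 3600 * design$sample_rate_fps))
}

#' @rdname frames_per_session
#' @export
n_blocks <- function(design) {
  as.integer(round(design$session_hours * 60 / design$block_duration_min))
}

#' @rdname frames_per_session
#' @export
frames_per_block <- function(design) {
  as.integer(round(design$block_duration_min * 60 * design$sample_rate_fps))
}

#' Average an index series into experimental blocks
#'
#' Assigns every frame to its 30-min (by default) block by timestamp and
#' averages the valid cluster and unrest values per block; invalid frames
#' are excluded from the means and counted. A frame exactly on the session
#' end boundary is counted in the final block.
#'
#' @param series an [compute_index_series()] result covering the session.
#' @param design an [experiment_design] object.
#' @param temperature,enrichment condition labels attached to every block.
#' @return Data frame with one row per block: `block_id`, `temperature`,
#'   `enrichment`, `mean_cluster`, `mean_unrest`, `n_valid_frames`
#'   (cluster), `n_valid_pairs` (unrest). Blocks with no valid values get
#'   `NA` means.
#' @export
block_averages <- function(series, design = experiment_design(),
                           temperature, enrichment) {
  stopifnot(inherits(series, "index_series"),
            inherits(design, "experiment_design"))
  block_len_s <- design$block_duration_min * 60
  nb <- n_blocks(design)
  session_s <- design$session_hours * 3600
  if (max(series$cluster$timestamp_s) < session_s - block_len_s)
    warning("index series does not cover the full session; ",
            "trailing blocks will be empty")
  blk <- function(ts) pmin(floor(ts / block_len_s) + 1L, nb)
  cb <- blk(series$cluster$timestamp_s)
  ub <- blk(series$unrest$timestamp_s)
  out <- lapply(seq_len(nb), function(b) {
    cv <- series$cluster$cluster_index[cb == b & series$cluster$valid]
    uv <- series$unrest$unrest_cm[ub == b & series$unrest$valid]
    data.frame(block_id = b, temperature = temperature,
               enrichment = enrichment,
               mean_cluster = if (length(cv)) mean(cv) else NA_real_,
               mean_unrest = if (length(uv)) mean(uv) else NA_real_,
               n_valid_frames = length(cv), n_valid_pairs = length(uv))
  })
  do.call(rbind, out)
}

response_column <- function(response = c("cluster", "unrest")) {
  switch(match.arg(response), cluster = "mean_cluster",
         unrest = "mean_unrest")
}

#' Split-plot-in-time ANOVA of block means
#'
#' Repeated-measures comparison of the block-averaged index across the
#' temperature x enrichment conditions: temperature is the whole-plot
#' factor, enrichment the subplot factor, and time blocks the repeated
#' measures. Fitted with `aov(y ~ temperature * enrichment +
#' Error(block/temperature))`: the temperature main effect is tested in the
#' block:temperature stratum, enrichment and the interaction in the within
#' stratum. Blocks with missing means are dropped listwise with a warning.
#' Effects with zero sum of squares are reported as `F = 0`, `p = 1`
#' (rather than 0/0).
#'
#' @param blocks row-bound [block_averages()] output across all
#'   conditions.
#' @param response `"cluster"` or `"unrest"`.
#' @return Data frame with one row per effect (`temperature`,
#'   `enrichment`, `temperature:enrichment`): `df`, `df_error`,
#'   `F`, `p`. The model formula is attached as attribute `"model"`.
#' @export
split_plot_anova <- function(blocks, response = c("cluster", "unrest")) {
  col <- response_column(response)
  df <- data.frame(y = blocks[[col]],
                   temperature = factor(blocks$temperature),
                   enrichment = factor(blocks$enrichment),
                   block = factor(blocks$block_id))
  if (nlevels(df$temperature) < 2L && nlevels(df$enrichment) < 2L)
    stop_input("need at least two conditions to compare")
  if (anyNA(df$y)) {
    warning(sum(is.na(df$y)), " block(s) with missing means dropped ",
            "from the ANOVA")
    df <- df[!is.na(df$y), ]
  }
  counts <- table(df$temperature, df$enrichment)
  if (any(counts < 2L))
    stop_input("need at least 2 blocks per condition")
  if (length(unique(counts)) > 1L)
    warning("unbalanced design: unequal block counts per condition")
  form <- y ~ temperature * enrichment + Error(block / temperature)
  fit <- aov(form, data = df)
  sm <- summary(fit)
  total_ss <- 0
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    total_ss <- total_ss + sum(tab[["Sum Sq"]])
    resid_row <- trimws(rownames(tab)) == "Residuals"
    df_err <- if (any(resid_row)) tab[resid_row, "Df"] else NA_real_
    ms_err <- if (any(resid_row)) tab[resid_row, "Mean Sq"] else NA_real_
    for (i in which(!resid_row)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = trimws(rownames(tab)[i]), df = tab[i, "Df"],
        df_error = df_err, ss = tab[i, "Sum Sq"],
        ms = tab[i, "Mean Sq"], ms_error = ms_err)
    }
  }
  out <- do.call(rbind, rows)
  eps <- 1e-12 * max(total_ss, 1)
  out$F <- ifelse(out$ss <= eps, 0,
                  ifelse(out$ms_error <= eps, Inf, out$ms / out$ms_error))
  out$p <- ifelse(out$ss <= eps, 1,
                  ifelse(out$ms_error <= eps, 0,
                         stats::pf(out$F, out$df, out$df_error,
                                   lower.tail = FALSE)))
  out <- out[, c("effect", "df", "df_error", "F", "p")]
  rownames(out) <- NULL
  attr(out, "model") <-
    "y ~ temperature * enrichment + Error(block/temperature)"
  out
}

assign_letters_by_rank <- function(means) {
  # degenerate fallback when the residual variance vanishes: equal means
  # share a letter, distinct means get distinct letters
  r <- match(round(means, 8), sort(unique(round(means, 8))))
  letters[r]
}

#' Tukey mean separation with compact letter display
#'
#' Per-condition means of the block-averaged index (plain arithmetic means
#' of the block means) with Tukey all-pairs comparisons at level `alpha`;
#' conditions sharing a letter are not significantly different. Comparisons
#' come from `multcomp::glht` on an `aov(y ~ block + condition)` fit; if
#' the fit is degenerate (zero residual variance) equal means share one
#' letter and distinct means get distinct letters.
#'
#' @param blocks row-bound [block_averages()] output across conditions.
#' @param response `"cluster"` or `"unrest"`.
#' @param alpha significance level in (0, 1), default 0.05.
#' @return Data frame: `condition`, `temperature`, `enrichment`, `mean`,
#'   `n_blocks`, `group` (letters).
#' @export
tukey_groups <- function(blocks, response = c("cluster", "unrest"),
                         alpha = 0.05) {
  col <- response_column(response)
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must lie in (0, 1)")
  df <- data.frame(y = blocks[[col]],
                   condition = factor(paste(blocks$temperature,
                                            blocks$enrichment, sep = ":")),
                   temperature = blocks$temperature,
                   enrichment = blocks$enrichment,
                   block = factor(blocks$block_id))
  df <- df[!is.na(df$y), ]
  if (nlevels(droplevels(df$condition)) < 2L)
    stop_input("need at least two conditions")
  df$condition <- droplevels(df$condition)
  agg <- aggregate(y ~ condition + temperature + enrichment, df, mean)
  nbl <- aggregate(y ~ condition, df, length)
  means <- setNames(agg$y, agg$condition)
  fit <- aov(y ~ block + condition, data = df)
  sigma <- sqrt(sum(stats::residuals(fit)^2) /
                  max(stats::df.residual(fit), 1))
  letters_by <- if (stats::df.residual(fit) < 1L || sigma < 1e-10 ||
                    !is.finite(sigma)) {
    assign_letters_by_rank(means)
  } else {
    glt <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Tukey"))
    cl <- multcomp::cld(glt, level = alpha)
    unname(cl$mcletters$Letters[as.character(agg$condition)])
  }
  out <- data.frame(condition = as.character(agg$condition),
                    temperature = agg$temperature,
                    enrichment = agg$enrichment,
                    mean = agg$y,
                    n_blocks = nbl$y[match(agg$condition, nbl$condition)],
                    group = letters_by)
  out[order(out$temperature, out$enrichment), ]
}

#' Condition report: indices by temperature and enrichment
#'
#' Prints a markdown-style table of per-condition means with Tukey letters
#' for both indices (index x temperature x enrichment layout) and returns
#' the two [tukey_groups()] tables.
#'
#' @param blocks row-bound [block_averages()] output across conditions.
#' @param alpha Tukey significance level.
#' @return Invisibly, `list(cluster = ..., unrest = ...)`.
#' @export
condition_report <- function(blocks, alpha = 0.05) {
  res <- list(cluster = tukey_groups(blocks, "cluster", alpha),
              unrest = tukey_groups(blocks, "unrest", alpha))
  cat(sprintf("| %-8s | %-12s | %-12s | %10s | %-6s |\n",
              "Index", "Temperature", "Environment", "Mean", "Group"))
  cat("|----------|--------------|--------------|------------|--------|\n")
  for (nm in names(res)) {
    tab <- res[[nm]]
    for (i in seq_len(nrow(tab)))
      cat(sprintf("| %-8s | %-12s | %-12s | %10.3f | %-6s |\n",
                  nm, tab$temperature[i], tab$enrichment[i], tab$mean[i],
                  tab$group[i]))
  }
  invisible(res)
}

#' Write block summaries to CSV
#'
#' @param blocks [block_averages()] output.
#' @param path output CSV path.
#' @return Invisibly, `blocks`.
#' @export
write_block_csv <- function(blocks, path) {
  write.csv(blocks, path, row.names = FALSE)
  invisible(blocks)
}
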