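#' Provider-level scorecards
#'
#' One scorecard per eligible provider: five panels, each carrying the
#' provider's value, the specialty median, the outlier threshold, the status,
#' and a color key (`"outlier"` for flagged bars, `"consistent"` otherwise,
#' `"median"` for the peer bar). Values are copied from the metrics and flag
#' tables, never recomputed.
#'
#' @param metrics,thresholds,flags Stage outputs for one quarter.
#' @return Named list of scorecards; each is a list with `provider_id`,
#'   `quarter`, `division`, `specialty`, and a 5-row `panels` tibble.
#' @export
build_provider_scorecards <- function(metrics, thresholds, flags) {
  med <- thresholds %>% select(division, specialty, metric, median)
  panels_all <- flags %>%
    left_join(med, by = c("division", "specialty", "metric")) %>%
    mutate(color_key = ifelse(status == "within", "consistent", "outlier"))
  split_panels <- split(panels_all, panels_all$provider_id)
  lapply(split_panels, function(p) {
    stopifnot(nrow(p) == 5)
    list(
      provider_id = p$provider_id[1],
      quarter = p$quarter[1],
      division = p$division[1],
      specialty = p$specialty[1],
      panels = p %>% select(metric, value, specialty_median = median,
                            outlier_threshold, status, color_key)
    )
  })
}

fd_bin_edges <- function(values, min_bins = 5) {
  rng <- range(values)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  iqr <- unname(diff(quantile(values, c(0.25, 0.75), type = 7)))
  width <- 2 * iqr / length(values)^(1 / 3)
  k <- if (width > 0) ceiling(diff(rng) / width) else min_bins
  k <- max(k, min_bins)
  seq(rng[1], rng[2], length.out = k + 1)
}

#' Leadership scorecard for one specialty within a division
#'
#' Summarises a specialty's distribution for its service-line leader or chair.
#' Each of the five metrics gets a page with: the number of providers included,
#' how many prescribed no opioids that quarter, how many prescribed within the
#' threshold, and how many were outliers (the three buckets partition the
#' group); a top-15 list ranked by value descending with ties broken by
#' provider id; the full scatter series; and Freedman-Diaconis histogram bins
#' (floored at 5 bins) with counts summing to the group size.
#'
#' @param division,specialty Group identifiers.
#' @param metrics,flags Stage outputs for one quarter.
#' @param top_n Length cap of the ranked list (default 15).
#' @return List with group identifiers and a `pages` list keyed by metric.
#' @export
build_leadership_scorecard <- function(division, specialty, metrics, flags, top_n = 15) {
  grp <- flags %>% filter(division == !!division, specialty == !!specialty)
  if (nrow(grp) == 0) {
    abort_fatal(sprintf("unknown group: %s / %s", division, specialty))
  }
  m1 <- grp %>% filter(metric == "m1_rx_count") %>% select(provider_id, m1 = value)
  pages <- lapply(split(grp, grp$metric), function(pg) {
    pg <- pg %>% left_join(m1, by = "provider_id")
    n_included <- nrow(pg)
    n_zero <- sum(pg$m1 == 0)
    n_outlier <- sum(pg$status != "within")
    n_within <- n_included - n_zero - n_outlier
    ranked <- pg %>% arrange(dplyr::desc(value), provider_id)
    top <- head(ranked, min(top_n, n_included)) %>%
      select(provider_id, value, status)
    edges <- fd_bin_edges(pg$value)
    cuts <- cut(pg$value, breaks = edges, include.lowest = TRUE, right = TRUE)
    list(
      metric = pg$metric[1],
      n_included = n_included,
      n_zero_prescribers = n_zero,
      n_within = n_within,
      n_outlier = n_outlier,
      top_providers = top,
      scatter = pg %>% arrange(provider_id) %>% select(provider_id, value, status),
      histogram = list(bin_edges = edges, counts = as.integer(table(cuts)))
    )
  })
  list(division = division, specialty = specialty,
       quarter = grp$quarter[1], pages = pages)
}

#' Leadership scorecards for every (division, specialty) group
#'
#' @inheritParams build_leadership_scorecard
#' @return Named list of [build_leadership_scorecard()] results, keyed
#'   `division__specialty`.
#' @export
build_leadership_scorecards <- function(metrics, flags, top_n = 15) {
  groups <- metrics %>% distinct(division, specialty)
  out <- Map(function(d, s) build_leadership_scorecard(d, s, metrics, flags, top_n),
             groups$division, groups$specialty)
  names(out) <- paste(groups$division, groups$specialty, sep = "__")
  out
}

#' Chief-medical-officer extreme-outlier report
#'
#' Tabular report of providers strictly above the extreme threshold (3x the
#' specialty outlier threshold by default) on at least one metric, for one
#' division or for the whole enterprise. Rows are sorted descending by the
#' provider's worst value-to-outlier-threshold ratio (a positive value over a
#' zero threshold sorts first).
#'
#' @param flags Output of [flag_providers()].
#' @param scope A division name, or `"enterprise"` for all divisions.
#' @param include_all_outliers If TRUE, plain outliers are listed too.
#' @return List with `scope`, `quarter`, and a wide `rows` tibble (one row per
#'   listed provider; per-metric value / thresholds / extreme flag columns).
#' @export
build_cmo_report <- function(flags, scope = "enterprise", include_all_outliers = FALSE) {
  f <- flags
  if (!identical(scope, "enterprise")) f <- f %>% filter(division == !!scope)
  wanted_status <- if (include_all_outliers) c("outlier", "extreme_outlier") else "extreme_outlier"
  hits <- f %>% group_by(provider_id) %>%
    mutate(listed = any(status %in% wanted_status)) %>% ungroup() %>%
    filter(listed)
  if (nrow(hits) == 0) {
    return(list(scope = scope, quarter = unique(flags$quarter)[1],
                rows = tibble(provider_id = character(), division = character(),
                              specialty = character(), max_ratio = numeric())))
  }
  wide <- hits %>%
    mutate(ratio = ifelse(outlier_threshold > 0, value / outlier_threshold,
                          ifelse(value > 0, Inf, 0))) %>%
    group_by(provider_id, quarter, division, specialty) %>%
    summarise(max_ratio = max(ratio), .groups = "drop")
  vals <- hits %>%
    select(provider_id, metric, value, outlier_threshold, extreme_threshold, status) %>%
    mutate(extreme = status == "extreme_outlier", status = NULL) %>%
    tidyr::pivot_wider(names_from = metric,
                       values_from = c(value, outlier_threshold, extreme_threshold, extreme))
  rows <- wide %>% left_join(vals, by = "provider_id") %>%
    arrange(dplyr::desc(max_ratio), provider_id)
  list(scope = scope, quarter = rows$quarter[1], rows = rows)
}

#' Assemble the full report bundle for one quarter
#'
#' @param metrics,thresholds,flags Stage outputs for one quarter.
#' @param config The run configuration (recorded in the bundle metadata so
#'   every report states the modes it was computed under).
#' @return A `scorecard_bundle` list: provider scorecards, leadership
#'   scorecards, CMO reports per division plus enterprise, and metadata.
#' @export
build_scorecard_bundle <- function(metrics, thresholds, flags,
                                   config = default_run_config(),
                                   quarter = NULL) {
  quarter <- quarter %||% unique(metrics$quarter)[1]
  if (is.na(quarter)) quarter <- "empty"
  divisions <- sort(unique(metrics$division))
  cmo <- lapply(divisions, function(d) build_cmo_report(flags, d))
  names(cmo) <- divisions
  cmo$enterprise <- build_cmo_report(flags, "enterprise")
  structure(list(
    quarter = quarter,
    providers = build_provider_scorecards(metrics, thresholds, flags),
    leadership = build_leadership_scorecards(metrics, flags),
    cmo = cmo,
    meta = list(threshold_mode = config$threshold_mode,
                outlier_k = config$outlier_k,
                extreme_multiplier = config$extreme_multiplier,
                metric4_unit = config$metric4_unit,
                metric5_unit = config$metric5_unit)
  ), class = "scorecard_bundle")
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "rows")
  invisible(path)
}

#' Render a scorecard bundle to disk
#'
#' Writes the deterministic, schema-stable data renderings: one JSON per
#' provider scorecard under `providers/`, one JSON per leadership scorecard
#' under `leadership/`, one CSV per CMO scope under `cmo/`, plus the bundle
#' metadata. Rendering the same bundle twice produces byte-identical files.
#' Chart images (bar/scatter/histogram) are a best-effort extra via
#' [render_charts()] and are not part of the stable surface.
#'
#' @param bundle A [build_scorecard_bundle()] result.
#' @param out_dir Output directory (created; a `quarter` subdirectory is used).
#' @return The quarter directory, invisibly.
#' @export
render_bundle <- function(bundle, out_dir) {
  qdir <- file.path(out_dir, bundle$quarter)
  for (d in c("providers", "leadership", "cmo")) {
    dir.create(file.path(qdir, d), recursive = TRUE, showWarnings = FALSE)
  }
  json_write(bundle$meta, file.path(qdir, "meta.json"))
  for (sc in bundle$providers) {
    json_write(sc, file.path(qdir, "providers", paste0(sc$provider_id, ".json")))
  }
  for (nm in names(bundle$leadership)) {
    json_write(bundle$leadership[[nm]], file.path(qdir, "leadership", paste0(nm, ".json")))
  }
  for (nm in names(bundle$cmo)) {
    rows <- bundle$cmo[[nm]]$rows
    write.csv(as.data.frame(rows), file.path(qdir, "cmo", paste0(nm, ".csv")),
              row.names = FALSE, na = "")
  }
  invisible(qdir)
}

#' Best-effort chart rendering for one leadership scorecard
#'
#' Draws the top-prescriber bar chart, the status-coded scatter, and the
#' histogram for each metric page as PNGs. Requires ggplot2; a no-op with a
#' message when it is unavailable.
#'
#' @param scorecard One element of [build_leadership_scorecards()].
#' @param out_dir Directory for the PNGs.
#' @return Paths written, invisibly.
#' @export
render_charts <- function(scorecard, out_dir) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    message("ggplot2 not installed; skipping chart rendering")
    return(invisible(character()))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (pg in scorecard$pages) {
    top <- pg$top_providers
    p1 <- ggplot2::ggplot(top, ggplot2::aes(
      x = stats::reorder(provider_id, -value), y = value, fill = status)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = pg$metric,
                    title = sprintf("%s / %s: top prescribers (%s)",
                                    scorecard$division, scorecard$specialty, pg$metric)) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
    p2 <- ggplot2::ggplot(pg$scatter, ggplot2::aes(
      x = seq_along(value), y = value, colour = status)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "provider", y = pg$metric) + ggplot2::theme_minimal()
    hist_df <- data.frame(
      mid = (pg$histogram$bin_edges[-1] + pg$histogram$bin_edges[-length(pg$histogram$bin_edges)]) / 2,
      n = pg$histogram$counts)
    p3 <- ggplot2::ggplot(hist_df, ggplot2::aes(x = mid, y = n)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = pg$metric, y = "providers") + ggplot2::theme_minimal()
    for (i in seq_along(list(p1, p2, p3))) {
      f <- file.path(out_dir, sprintf("%s_%d.png", pg$metric, i))
      suppressMessages(ggplot2::ggsave(f, list(p1, p2, p3)[[i]],
                                       width = 7, height = 4, dpi = 96))
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}
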