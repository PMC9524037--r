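#' Quantify one field end to end
#'
#' The full per-field chain: segment the plaque, glial and nuclear
#' channels, measure plaques, call marker-positive cells by nucleus /
#' glial overlap, dilate plaques to the association radius and count
#' associated cells.
#'
#' @param field A [field_image()] with `plaque`, `glial` and `nuclear`
#'   channels.
#' @param radius_um Association radius in micrometres (20 for
#'   microglia, 50 for astrocytes by convention).
#' @param marker Marker label recorded on the cell table.
#' @param threshold `"otsu"` or a fixed numeric threshold applied to
#'   every channel.
#' @param min_area_um2 Minimum object area for segmentation.
#' @param overlap_rule Positivity rule, see [detect_positive_cells()].
#' @param interpretation Dilation semantics, see [dilate_labels()].
#' @return List of class `field_quantification`: `plaque_table`,
#'   `cells`, `association`, and the intermediate `masks`.
#' @export
quantify_field <- function(field, radius_um = 20, marker = "glial",
                           threshold = "otsu", min_area_um2 = 10,
                           overlap_rule = "any_pixel",
                           interpretation = "radius") {
  stopifnot(inherits(field, "field_image"))
  need <- c("plaque", "glial", "nuclear")
  if (!all(need %in% names(field$channels)))
    stop("field needs channels: ", paste(need, collapse = ", "))
  seg <- function(ch) {
    if (identical(threshold, "otsu"))
      segment_channel(ch, field$pixel_size, method = "otsu",
                      min_area_um2 = min_area_um2)
    else
      segment_channel(ch, field$pixel_size, method = "fixed",
                      threshold = threshold, min_area_um2 = min_area_um2)
  }
  plaques <- seg(field$channels$plaque)
  glia <- seg(field$channels$glial)
  nuclei <- seg(field$channels$nuclear)
  ptab <- quantify_plaques(plaques, field$channels$plaque)
  cells <- detect_positive_cells(glia, nuclei, marker = marker,
                                 rule = overlap_rule)
  zones <- dilate_labels(plaques, radius_um, interpretation = interpretation)
  assoc <- count_associated_cells(cells, nuclei, zones)
  structure(
    list(field_id = field$field_id, region = field$region, group = field$group,
         plaque_table = ptab, cells = cells, association = assoc,
         masks = list(plaques = plaques, glia = glia, nuclei = nuclei,
                      zones = zones)),
    class = "field_quantification")
}

#' @export
print.field_quantification <- function(x, ...) {
  cat(sprintf("field_quantification '%s': %d plaque(s), %d positive cell(s), %d associated\n",
              x$field_id, x$plaque_table$field$plaque_count,
              x$association$n_cells_total, x$association$n_cells_associated))
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates synthetic generation -> image quantification ->
#' expression processing -> group statistics from a single YAML file or
#' an equivalent nested list, writing CSV/JSON tables and a JSON-lines
#' run log into `out_dir`.  All randomness derives from `seed`, so a
#' second run with the same configuration produces byte-identical
#' tables.  Stages without configuration are skipped with a log notice;
#' missing input files are enumerated before any stage runs.
#'
#' Configuration keys (all optional except `out_dir`):
#' \describe{
#'   \item{`seed`}{Base integer seed (default 1).}
#'   \item{`images`}{`n_fields_per_group`, `groups` (character vector),
#'     `scene` (arguments for [random_scene_spec()]), `radius_um`,
#'     `marker`, `threshold` (`"otsu"` or a number), `min_area_um2`; or
#'     `files`, a list of TIFF paths readable by [read_field_tiff()].}
#'   \item{`expression`}{either `sim` (arguments for [expr_sim_spec()])
#'     or `files` (`counts`, `groups` CSVs); `disease_contrast`,
#'     `treatment_contrast` (2-vectors, A vs B), `fc_up`, `fc_down`,
#'     `alpha`, `background_k`.}
#' }
#'
#' @param config Path to a YAML file or a nested list.
#' @param out_dir Output directory (created if absent); overrides any
#'   `out_dir` in the config.
#' @return Invisible list with elements `fields` (per-field
#'   quantifications), `group_stats`, `expression` (normalized matrix,
#'   DE tables, reversal summary) and `outputs` (paths written).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("`out_dir` must be given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  log_path <- file.path(out_dir, "run_log.jsonl")
  unlink(log_path)
  log_line <- function(...) {
    rec <- list(...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  log_line(step = "start", package = "plaqglia",
           version = as.character(utils::packageVersion("plaqglia")),
           seed = seed)
  # fail early on missing inputs
  missing_files <- character(0)
  if (!is.null(config$images$files))
    missing_files <- c(missing_files,
                       Filter(Negate(file.exists), unlist(config$images$files)))
  if (!is.null(config$expression$files))
    missing_files <- c(missing_files,
                       Filter(Negate(file.exists), unlist(config$expression$files)))
  if (length(missing_files))
    stop("missing input files: ", paste(missing_files, collapse = ", "))

  outputs <- character(0)
  result <- list(fields = NULL, group_stats = NULL, expression = NULL)

  if (!is.null(config$images)) {
    ic <- config$images
    radius <- if (!is.null(ic$radius_um)) ic$radius_um else 20
    marker <- if (!is.null(ic$marker)) ic$marker else "glial"
    thr <- if (!is.null(ic$threshold)) ic$threshold else "otsu"
    min_area <- if (!is.null(ic$min_area_um2)) ic$min_area_um2 else 10
    fields <- list()
    if (!is.null(ic$files)) {
      for (f in ic$files) fields[[length(fields) + 1L]] <- read_field_tiff(f)
    } else {
      groups <- if (!is.null(ic$groups)) ic$groups else "group1"
      n_per <- if (!is.null(ic$n_fields_per_group)) ic$n_fields_per_group else 2L
      scene_args <- if (!is.null(ic$scene)) ic$scene else list()
      if (!is.null(scene_args$field_shape))
        scene_args$field_shape <- as.integer(unlist(scene_args$field_shape))
      k <- 0L
      for (g in groups) for (i in seq_len(n_per)) {
        k <- k + 1L
        sc <- do.call(random_scene_spec,
                      c(list(seed = (seed * 1009L + k) %% 2147483647L), scene_args))
        fld <- render_scene(sc)$field
        fld$field_id <- sprintf("%s_field%02d", g, i)
        fld$group <- g
        fields[[k]] <- fld
      }
    }
    quants <- lapply(fields, quantify_field, radius_um = radius,
                     marker = marker, threshold = thr, min_area_um2 = min_area)
    field_summary <- do.call(rbind, lapply(quants, function(q) {
      cbind(data.frame(field_id = q$field_id, region = q$region,
                       group = q$group, marker = marker),
            q$plaque_table$field,
            data.frame(n_cells_positive = q$association$n_cells_total,
                       n_cells_associated = q$association$n_cells_associated,
                       radius_um = q$association$radius_um))
    }))
    plaque_rows <- do.call(rbind, lapply(quants, function(q)
      if (nrow(q$plaque_table$plaques))
        cbind(field_id = q$field_id, q$plaque_table$plaques)))
    cell_rows <- do.call(rbind, lapply(quants, function(q)
      if (nrow(q$association$cells))
        cbind(field_id = q$field_id, q$association$cells)))
    w <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      outputs <<- c(outputs, p)
    }
    w(field_summary, "field_summary.csv")
    if (!is.null(plaque_rows)) w(plaque_rows, "plaque_table.csv")
    if (!is.null(cell_rows)) w(cell_rows, "cell_table.csv")
    log_line(step = "imquant", n_fields = length(quants), radius_um = radius,
             threshold = if (is.numeric(thr)) thr else "otsu",
             min_area_um2 = min_area)
    result$fields <- quants
    # group statistics on the standard field-level measures
    if (length(unique(field_summary$group)) >= 2L &&
        all(table(field_summary$group) >= 2L)) {
      measures <- c("plaque_count", "total_plaque_area_um2",
                    "percent_area_covered", "n_cells_positive",
                    "n_cells_associated")
      stats_rows <- list()
      gs <- list()
      for (msr in measures) {
        cmp <- compare_groups(field_summary[[msr]], field_summary$group,
                              measure = msr)
        gs[[msr]] <- cmp
        stats_rows[[msr]] <- data.frame(
          measure = msr, test = cmp$test, statistic = cmp$statistic,
          p_value = cmp$p_value, stars = cmp$stars)
      }
      w(do.call(rbind, stats_rows), "group_comparisons.csv")
      log_line(step = "group_stats", measures = measures)
      result$group_stats <- gs
    }
  } else {
    log_line(step = "imquant", skipped = TRUE,
             reason = "no image configuration")
  }

  if (!is.null(config$expression)) {
    ec <- config$expression
    if (!is.null(ec$sim)) {
      sim_args <- ec$sim
      if (!is.null(sim_args$groups)) sim_args$groups <- unlist(sim_args$groups)
      sim_args$seed <- if (!is.null(sim_args$seed)) sim_args$seed else seed
      sim <- simulate_expression(do.call(expr_sim_spec, sim_args))
      m <- sim$matrix
    } else if (!is.null(ec$files)) {
      m <- read_expression_csv(ec$files$counts, ec$files$groups)
    } else stop("expression stage needs `sim` or `files`")
    k_bg <- if (!is.null(ec$background_k)) ec$background_k else 2
    if (length(m$negative_controls)) m <- background_subtract(m, k = k_bg)
    m_norm <- normalize_housekeeping(m)
    norm_path <- file.path(out_dir, "normalized_counts.csv")
    grp_path <- file.path(out_dir, "sample_groups.csv")
    write_expression_csv(m_norm, norm_path, grp_path)
    outputs <- c(outputs, norm_path, grp_path)
    fc_up <- if (!is.null(ec$fc_up)) ec$fc_up else 1.5
    fc_down <- if (!is.null(ec$fc_down)) ec$fc_down else 0.66
    alpha <- if (!is.null(ec$alpha)) ec$alpha else 0.05
    expr_out <- list(normalized = m_norm)
    de_dis <- NULL
    if (!is.null(ec$disease_contrast)) {
      de_dis <- differential_expression(m_norm, unlist(ec$disease_contrast),
                                        fc_up = fc_up, fc_down = fc_down,
                                        alpha = alpha)
      p <- file.path(out_dir, "de_disease.csv")
      utils::write.csv(de_dis, p, row.names = FALSE); outputs <- c(outputs, p)
      p <- file.path(out_dir, "volcano_disease.csv")
      utils::write.csv(volcano_table(de_dis), p, row.names = FALSE)
      outputs <- c(outputs, p)
      expr_out$de_disease <- de_dis
    }
    if (!is.null(ec$treatment_contrast)) {
      de_tr <- differential_expression(m_norm, unlist(ec$treatment_contrast),
                                       fc_up = fc_up, fc_down = fc_down,
                                       alpha = alpha)
      p <- file.path(out_dir, "de_treatment.csv")
      utils::write.csv(de_tr, p, row.names = FALSE); outputs <- c(outputs, p)
      expr_out$de_treatment <- de_tr
      if (!is.null(de_dis)) {
        rev <- reversal_analysis(de_dis, de_tr)
        p <- file.path(out_dir, "reversal_summary.json")
        jsonlite::write_json(list(n_deg = rev$n_deg, n_reversed = rev$n_reversed,
                                  fraction = rev$fraction),
                             p, auto_unbox = TRUE, digits = NA)
        outputs <- c(outputs, p)
        expr_out$reversal <- rev
      }
    }
    log_line(step = "expr", n_genes = nrow(m$counts),
             n_samples = ncol(m$counts), fc_up = fc_up, fc_down = fc_down,
             alpha = alpha)
    result$expression <- expr_out
  } else {
    log_line(step = "expr", skipped = TRUE, reason = "no expression configuration")
  }

  log_line(step = "done", outputs = basename(outputs))
  result$outputs <- outputs
  invisible(result)
}
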