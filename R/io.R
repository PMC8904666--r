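# File formats: response matrices and crosswalks as CSV (crosswalks carry
# '#' metadata comment lines), item parameters as JSON or CSV, run
# configuration as YAML.

#' Read a wide-format ordinal response matrix
#'
#' CSV with a header of item ids, one row per respondent, empty cell =
#' missing. Optional `id` and `subgroup` columns are carried through. Codes
#' are validated against each scale's range; violations name the cell.
#'
#' @param path CSV path.
#' @param scales List of [scale_def()] whose items must all be present.
#' @return Validated response data frame.
#' @export
read_responses <- function(path, scales) {
  if (inherits(scales, "scale_def")) scales <- list(scales)
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("", "NA"))
  items <- unlist(lapply(scales, `[[`, "items"))
  miss <- setdiff(items, names(df))
  if (length(miss))
    stop("file lacks item column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c("id", "subgroup", items))
  if (length(extra))
    stop("unknown item column(s): ", paste(extra, collapse = ", "))
  for (it in items) {
    v <- df[[it]]
    if (!is.numeric(v) || any(!is.na(v) & v != round(v)))
      stop("non-integer code(s) in column '", it, "'")
    df[[it]] <- as.integer(v)
  }
  for (sc in scales) check_codes(as.matrix(df[, sc$items, drop = FALSE]), sc)
  df
}

#' @rdname read_responses
#' @param responses Response data frame.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, na = "")
  invisible(path)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) sprintf("%.10g", v), character(1)))
}

#' Write / read a crosswalk CSV
#'
#' Columns `raw, t, se_t, anchor_raw`, preceded by `#` comment lines carrying
#' the provenance metadata (method, target, anchor, anchor metric). Reading
#' validates that the t column is non-decreasing; a write-read-write round
#' trip is byte-identical.
#'
#' @param xw A `crosswalk`.
#' @param path CSV path.
#' @export
write_crosswalk <- function(xw, path) {
  hdr <- c(paste0("# method: ", attr(xw, "method")),
           paste0("# target: ", attr(xw, "target")),
           paste0("# anchor: ", attr(xw, "anchor")),
           paste0("# anchor_metric: ", attr(xw, "anchor_metric")))
  body <- paste(xw$raw, fmt_num(xw$t), fmt_num(xw$se_t),
                fmt_num(xw$anchor_raw), sep = ",")
  writeLines(c(hdr, "raw,t,se_t,anchor_raw", body), path)
  invisible(path)
}

#' @rdname write_crosswalk
#' @export
read_crosswalk <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        na.strings = c("", "NA"))
  if (is.unsorted(df$t))
    stop("integrity error: crosswalk t column is not non-decreasing")
  new_crosswalk(df, meta$method %||% "unknown", meta$target %||% "target",
                meta$anchor %||% "anchor",
                meta$anchor_metric %||% meta$anchor %||% "anchor")
}

#' Item parameters as JSON or CSV
#'
#' JSON is a list of `{item, a, b: [...]}` records; CSV is wide with columns
#' `item, a, b1, b2, ...` (trailing thresholds empty for items with fewer
#' categories).
#'
#' @param params List of [item_params()].
#' @param path Output path (`.json` or `.csv` chosen by extension).
#' @export
write_item_params <- function(params, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(params, function(p) list(item = p$item, a = p$a, b = p$b))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    kmax <- max(vapply(params, function(p) length(p$b), integer(1)))
    rows <- lapply(params, function(p)
      c(p$item, fmt_num(c(p$a, p$b, rep(NA, kmax - length(p$b))))))
    m <- do.call(rbind, rows)
    colnames(m) <- c("item", "a", paste0("b", seq_len(kmax)))
    utils::write.csv(as.data.frame(m), path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_item_params
#' @export
read_item_params <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    lapply(recs, function(r) item_params(r$item, r$a, unlist(r$b)))
  } else {
    df <- utils::read.csv(path, na.strings = c("", "NA"))
    lapply(seq_len(nrow(df)), function(i) {
      b <- as.numeric(df[i, -(1:2)])
      item_params(df$item[i], as.numeric(df$a[i]), b[!is.na(b)])
    })
  }
}

#' Published reference crosswalks
#'
#' The three crosswalks shipped with the package (PFI-WE and MZSIB to the
#' MBI-EE metric; PFI-ID to the MBI-DP metric), as published for US
#' physicians. Used for the worked examples and the cut-point tools; the
#' anchor metrics derive from a 2014 national physician calibration of the
#' MBI, so item sets on the EE metric cannot be compared with the DP one.
#'
#' @param set One of `"pfi_we"`, `"pfi_id"`, `"mzsib"`.
#' @return A `crosswalk`.
#' @export
published_crosswalk <- function(set = c("pfi_we", "pfi_id", "mzsib")) {
  set <- match.arg(set)
  f <- c(pfi_we = "crosswalk_pfi_we_mbi_ee.csv",
         pfi_id = "crosswalk_pfi_id_mbi_dp.csv",
         mzsib = "crosswalk_mzsib_mbi_ee.csv")[[set]]
  read_crosswalk(system.file("extdata", f, package = "burnoutlink",
                             mustWork = TRUE))
}

#' Published anchor cut-points
#'
#' Commonly used raw cut-points on the anchor scales and their t-scores on
#' the 2014 physician calibration metric: emotional exhaustion raw >= 27
#' (t = 50.70) and depersonalization raw >= 10 (t = 53.76).
#'
#' @return Data frame `scale, raw_cut, t_cut`.
#' @export
anchor_cutpoints <- function() {
  data.frame(scale = c("MBI-EE", "MBI-DP"),
             raw_cut = c(27L, 10L),
             t_cut = c(50.70, 53.76))
}

#' Read a YAML run configuration
#'
#' @param path YAML file defining scales, item-parameter sources, linking
#'   method(s), `k` for cross-validation, seeds, cut-points, and the output
#'   directory. See the vignette for the schema.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

#' Run the full linking pipeline
#'
#' Missingness filter, assumption checks, both linking methods under k-fold
#' cross-validation, method selection, full-sample crosswalks from the
#' selected method, cut-point equivalencies, and reliability curves; all
#' artifacts are written as CSV/JSON with seeds recorded in the run log.
#'
#' @param iset An [item_set()].
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param methods Linking methods to evaluate.
#' @param k Folds for cross-validation.
#' @param seed Integer seed.
#' @param cut_t,cut_raw Anchor cut-point (optional; enables the cut-point
#'   stage).
#' @param grid Quadrature nodes.
#' @param control Passed to [grm_calibrate()].
#' @return List with `assumptions`, `cv` (per method), `selection`,
#'   `crosswalk` (selected method, full sample), `cutpoint` (if a cut was
#'   given), `reliability` (target and anchor curves), and `log`.
#' @export
run_pipeline <- function(iset, out_dir = NULL,
                         methods = c("irt", "equipercentile"), k = 5L,
                         seed = 1L, cut_t = NULL, cut_raw = NULL,
                         grid = quad_grid(), control = list()) {
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- list(stage = stage, time = format(Sys.time()),
                                     detail = paste0(...))
  }
  note("filter", "missingness rule <=1 per scale")
  flt <- filter_missingness(iset$responses, list(iset$target, iset$anchor))
  note("filter", "excluded ", flt$n_excluded, " respondent(s)")

  assum <- assumption_check(iset)
  note("assumptions", sprintf("r = %.3f, eigen ratio = %.2f",
                              assum$pearson_r, assum$eigen_ratio))

  cvs <- lapply(methods, function(m)
    kfold_cv(iset, k = k, method = m, seed = seed, grid = grid,
             control = control))
  names(cvs) <- methods
  acc <- do.call(rbind, lapply(methods, function(m)
    data.frame(method = m, item_set = paste(iset$target$name, "->",
                                            iset$anchor$name),
               r = cvs[[m]]$r, mean_diff = cvs[[m]]$mean_diff,
               sd_diff = cvs[[m]]$sd_diff)))
  sel <- select_method(acc)
  chosen <- if (is.na(sel$method)) methods[1] else sel$method
  note("selection", "status ", sel$status, "; using ", chosen)

  xw <- if (chosen == "irt") {
    irt_link(iset, grid = grid, control = control)
  } else {
    tab <- summed_score_eap(iset$anchor_params, latent_density(0, 1), grid,
                            iset$anchor$lowest_code)
    equipercentile_link(flt$totals[[iset$target$name]],
                        flt$totals[[iset$anchor$name]], tab,
                        target_range = c(iset$target$min_raw,
                                         iset$target$max_raw),
                        anchor_range = c(iset$anchor$min_raw,
                                         iset$anchor$max_raw),
                        target = iset$target$name, anchor = iset$anchor$name,
                        anchor_metric = iset$anchor_metric)
  }
  cut <- if (!is.null(cut_t) || !is.null(cut_raw)) {
    closest_cutpoint(xw, cut_t = cut_t, cut_raw = cut_raw)
  }
  rel <- list(
    target = if (!iset$self && chosen == "irt")
      reliability_curve(attr(xw, "extra")$target_params,
                        scale_name = iset$target$name),
    anchor = reliability_curve(iset$anchor_params,
                               scale_name = iset$anchor$name))
  note("done", "seed ", seed)

  out <- list(assumptions = assum, cv = cvs, selection = sel, crosswalk = xw,
              cutpoint = cut, reliability = rel, seed = seed, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_crosswalk(xw, file.path(out_dir, "crosswalk.csv"))
    utils::write.csv(acc, file.path(out_dir, "cv_accuracy.csv"),
                     row.names = FALSE)
    if (!is.null(rel$anchor))
      utils::write.csv(rel$anchor, file.path(out_dir, "reliability_anchor.csv"),
                       row.names = FALSE)
    if (!is.null(rel$target))
      utils::write.csv(rel$target, file.path(out_dir, "reliability_target.csv"),
                       row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, selection = sel$status, method = chosen,
           assumptions = list(pearson_r = assum$pearson_r,
                              eigen_ratio = assum$eigen_ratio),
           log = log),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
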