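#' Read a grayscale image from PNG, TIFF or PGM
#'
#' Color images are collapsed to luminance (0.299 R + 0.587 G + 0.114 B).
#' Intensities are returned as float64 in [0, 1] (integer-coded formats are
#' divided by their type maximum), so 8-bit and 16-bit sources are
#' numerically uniform downstream.
#'
#' @param path file path; format is taken from the extension
#'   (.png, .tif/.tiff, .pgm).
#' @return numeric matrix in [0, 1].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                pgm = read_pgm(path),
                stop("unsupported image format: .", ext))
  to_grayscale(arr)
}

# Collapse an H x W x C array to luminance; pass matrices through.
to_grayscale <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3]
    if (ch >= 3L)
      return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
    return(arr[, , 1])
  }
  stop("unrecognized image array layout")
}

# Minimal PGM reader (ASCII P2 and binary P5); no installed R package
# handles PGM. Values are scaled by the header maxval.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header")
      if (ch == "#") {               # comment runs to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval < 256L) {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
  }
  if (length(vals) != n) stop("truncated PGM pixel data")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a matrix as an 8-bit PGM (ASCII) image
#'
#' Intended for inspecting synthetic fixtures; values are clipped to [0, 1]
#' and quantized to 255 levels.
#'
#' @param image numeric matrix.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_pgm <- function(image, path) {
  q <- round(pmax(pmin(image, 1), 0) * 255)
  lines <- c("P2", paste(ncol(image), nrow(image)), "255",
             apply(q, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Load a labeled image directory
#'
#' Expects two subdirectories, \code{normal/} (label -1) and
#' \code{abnormal/} (label +1), each holding PNG/TIFF/PGM files. Unreadable
#' files are skipped with a warning; an empty result is an error.
#'
#' @param dir root directory.
#' @return list with \code{images}, \code{labels}, \code{ids}.
#' @export
load_image_dir <- function(dir) {
  images <- list(); labels <- numeric(); ids <- character()
  n_skipped <- 0L
  for (cls in c("normal", "abnormal")) {
    sub <- file.path(dir, cls)
    if (!dir.exists(sub)) next
    for (f in sort(list.files(sub, full.names = TRUE))) {
      img <- tryCatch(read_image(f), error = function(e) {
        warning("skipping unreadable image ", f, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(img)) { n_skipped <- n_skipped + 1L; next }
      images[[length(images) + 1L]] <- img
      labels <- c(labels, if (cls == "abnormal") 1 else -1)
      ids <- c(ids, file.path(cls, basename(f)))
    }
  }
  if (length(images) == 0L)
    stop("no usable images under ", dir,
         " (expected normal/ and abnormal/ subdirectories)")
  if (n_skipped > 0L)
    message(length(images), " images loaded, ", n_skipped, " skipped")
  list(images = images, labels = labels, ids = ids)
}

#' Experiment configuration
#'
#' Gathers every knob of one classification experiment in a single
#' serializable object: the input source (an image directory or a
#' [synth_config()]), the feature definition, the SVM and the evaluation
#' protocol. Round-trips losslessly through JSON via [write_run_config()] /
#' [read_run_config()].
#'
#' @param input_dir labeled image directory (see [load_image_dir()]), or
#'   NULL to use \code{synth}.
#' @param synth a [synth_config()] used when \code{input_dir} is NULL.
#' @param mode,level,n_bins feature definition, see [texture_features()].
#' @param bank a [gabor_bank()].
#' @param cost,degree SVM hyperparameters.
#' @param protocol,seed evaluation protocol, see [cross_validate()].
#' @return an object of class \code{"run_config"}.
#' @export
run_config <- function(input_dir = NULL, synth = synth_config(),
                       mode = "dwt_gabor", level = 1L, n_bins = 256L,
                       bank = gabor_bank(), cost = 1, degree = 2L,
                       protocol = "tenfold", seed = 1L) {
  mode <- match.arg(mode, c("dwt_gabor", "dwt", "gabor"))
  protocol <- match.arg(protocol, c("tenfold", "loocv"))
  structure(list(input_dir = input_dir, synth = synth, mode = mode,
                 level = as.integer(level), n_bins = as.integer(n_bins),
                 bank = bank, cost = cost, degree = as.integer(degree),
                 protocol = protocol, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{"run_config"}.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$synth <- unclass(x$synth)
  x$bank <- unclass(x$bank)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bank <- do.call(gabor_bank, x$bank[c("frequencies", "orientations",
                                       "sigma_x", "sigma_y", "nsigma",
                                       "freq_scale")])
  synth <- do.call(synth_config, x$synth)
  run_config(input_dir = x$input_dir, synth = synth, mode = x$mode,
             level = x$level, n_bins = x$n_bins, bank = bank,
             cost = x$cost, degree = x$degree, protocol = x$protocol,
             seed = x$seed)
}

# Resolve the input source of a run_config into images/labels/ids.
resolve_input <- function(config) {
  if (!is.null(config$input_dir)) load_image_dir(config$input_dir)
  else synth_dataset(config$synth)
}

#' Run one end-to-end classification experiment
#'
#' Loads or generates the images, extracts features in the configured mode,
#' runs cross-validated SVM classification, and (optionally) writes all
#' artifacts -- resolved configuration, feature table, per-fold metrics,
#' summary and log -- to an output directory. Fully deterministic given the
#' configuration seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed), or NULL to skip
#'   writing.
#' @param folds optional precomputed fold assignment (see
#'   [cross_validate()]).
#' @return list with \code{report} (a \code{"cv_report"}) and
#'   \code{features} (data frame: image_id, label, mode, level, then one
#'   column per feature).
#' @export
run_experiment <- function(config, out_dir = NULL, folds = NULL) {
  stopifnot(inherits(config, "run_config"))
  data <- resolve_input(config)
  rep <- cv_dwtgabor(data$images, data$labels, mode = config$mode,
                     level = config$level, bank = config$bank,
                     n_bins = config$n_bins, cost = config$cost,
                     degree = config$degree, protocol = config$protocol,
                     seed = config$seed, folds = folds)
  feats <- attr(rep, "features")
  ftab <- data.frame(image_id = data$ids, label = data$labels,
                     mode = config$mode,
                     level = if (config$mode == "gabor") NA_integer_
                             else config$level,
                     feats, check.names = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_run_config(config, file.path(out_dir, "config.json"))
    utils::write.csv(ftab, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$per_fold, file.path(out_dir, "per_fold.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(protocol = rep$protocol, seed = rep$seed, C = rep$cost,
           d = rep$degree, mean = as.list(rep$mean), sd = as.list(rep$sd),
           pooled = as.list(rep$pooled)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
    writeLines(c(
      sprintf("mode=%s level=%s", config$mode, config$level),
      sprintf("wavelet=%s boundary=symmetric", db4_wavelet()$name),
      sprintf("bank: f={%s} theta={%s} sigma_x=%g sigma_y=%g (frequency-major order)",
              paste(config$bank$frequencies, collapse = ","),
              paste(round(config$bank$orientations, 4), collapse = ","),
              config$bank$sigma_x, config$bank$sigma_y),
      sprintf("n_bins=%d log_base=2", config$n_bins),
      sprintf("svm: C=%g d=%d", config$cost, config$degree),
      sprintf("protocol=%s seed=%d n_images=%d", config$protocol,
              config$seed, length(data$images))),
      file.path(out_dir, "run.log"))
  }
  list(report = rep, features = ftab)
}

#' Compare the three feature modes on identical folds
#'
#' Runs DWT (levels 1 and 2), DWT-Gabor (levels 1 and 2) and Gabor-only on
#' the same images with the same fold assignment, so metric differences are
#' attributable to the features alone. This is the package's replication of
#' the method-by-level experimental design.
#'
#' @param config a [run_config()]; its \code{mode}/\code{level} are
#'   ignored, all five variants are run.
#' @param levels DWT levels to include (default 1:2).
#' @param out_dir optional output directory; each variant is written to a
#'   subdirectory, the comparison table to \code{comparison.csv}.
#' @return data frame with columns \code{mode}, \code{level},
#'   \code{CCR_mean}, \code{CCR_sd}, \code{Se_mean}, \code{Se_sd},
#'   \code{Sp_mean}, \code{Sp_sd} (percent); the per-variant
#'   \code{"cv_report"}s are attached as attribute \code{"reports"} and the
#'   shared fold assignment as attribute \code{"folds"}.
#' @export
compare_modes <- function(config, levels = 1:2, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  data <- resolve_input(config)
  folds <- if (config$protocol == "tenfold")
    stratified_folds(data$labels, 10L, config$seed)
  else seq_along(data$labels)
  variants <- c(lapply(levels, function(l) list(mode = "dwt", level = l)),
                lapply(levels, function(l) list(mode = "dwt_gabor", level = l)),
                list(list(mode = "gabor", level = NA_integer_)))
  reports <- list()
  rows <- list()
  for (v in variants) {
    cfg_v <- config
    cfg_v$mode <- v$mode
    cfg_v$level <- if (is.na(v$level)) 1L else as.integer(v$level)
    key <- if (v$mode == "gabor") "gabor" else sprintf("%s_L%d", v$mode, v$level)
    res <- run_experiment(cfg_v, folds = folds,
                          out_dir = if (is.null(out_dir)) NULL
                                    else file.path(out_dir, key))
    reports[[key]] <- res$report
    rows[[key]] <- data.frame(
      mode = v$mode, level = v$level,
      CCR_mean = 100 * res$report$mean[["ccr"]],
      CCR_sd = 100 * res$report$sd[["ccr"]],
      Se_mean = 100 * res$report$mean[["sensitivity"]],
      Se_sd = 100 * res$report$sd[["sensitivity"]],
      Sp_mean = 100 * res$report$mean[["specificity"]],
      Sp_sd = 100 * res$report$sd[["specificity"]])
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  attr(tab, "reports") <- reports
  attr(tab, "folds") <- folds
  tab
}
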