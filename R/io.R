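#' Read a spike raster from disk
#'
#' Supported formats: plain delimited text (one time bin per row, 0/1 entries
#' separated by whitespace or commas) and an RDS binary matrix container.
#' `format = "auto"` dispatches on the file extension (`.rds` vs anything
#' else).
#'
#' @param path File path.
#' @param format `"auto"`, `"txt"`, or `"rds"`.
#' @param bin_width_s Bin width to attach for text files (RDS files carry
#'   their own).
#' @return A `spike_raster`.
#' @export
read_raster <- function(path, format = c("auto", "txt", "rds"),
                        bin_width_s = 0.02) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "txt"
  }
  if (format == "rds") {
    obj <- readRDS(path)
    return(if (inherits(obj, "spike_raster")) obj else
      spike_raster(obj, bin_width_s))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty raster file: ", path)
  rows <- lapply(lines, function(l) strsplit(trimws(l), "[,[:space:]]+")[[1]])
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) stop("ragged rows in raster file: ", path)
  m <- matrix(NA_real_, length(rows), ncols)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    bad <- which(is.na(v) | !(v == 0 | v == 1))
    if (length(bad) > 0L) {
      stop(sprintf("non-binary entry '%s' at row %d, column %d of %s",
                   rows[[i]][bad[1L]], i, bad[1L], path))
    }
    m[i, ] <- v
  }
  spike_raster(m, bin_width_s)
}

#' Write a spike raster to disk
#'
#' @param raster A `spike_raster` or binary matrix.
#' @param path Output path; a `.rds` extension selects the binary container,
#'   anything else space-delimited text.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  x <- as_raster_matrix(raster)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(if (inherits(raster, "spike_raster")) raster else spike_raster(x),
            path)
  } else {
    utils::write.table(x, path, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a fitted model to JSON
#'
#' Models serialize to a JSON object with 17-significant-digit decimal
#' parameters, so a round trip preserves log-weights bit-for-bit. The
#' `model_class` tag (`"maxent"` or `"ri"`) dispatches the reader. Neuron
#' indices are stored 1-based, as used throughout the package.
#'
#' @param model A `maxent_model` or `ri_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "maxent_model")) {
    obj <- list(model_class = "maxent", n_neurons = model$n_neurons,
                features = lapply(model$features, as.integer),
                theta = model$theta, log_z = model$log_z,
                z_method = model$z_method)
  } else if (inherits(model, "ri_model")) {
    obj <- list(model_class = "ri", n_neurons = model$n_neurons,
                features = lapply(model$features, as.integer),
                theta = model$theta, z_ri = model$z_ri, p_min = model$p_min)
  } else {
    stop("model must be a maxent_model or ri_model")
  }
  # I(17) = 17 *significant* digits: enough to reproduce any double exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path Path to a JSON file written by [write_model()].
#' @return A `maxent_model` or `ri_model`, depending on its `model_class`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path)  # no simplification: features stay a list
  if (is.null(obj$model_class)) stop("missing model_class field in ", path)
  feats <- lapply(obj$features, function(f) as.integer(unlist(f)))
  theta <- as.numeric(unlist(obj$theta))
  if (identical(obj$model_class, "maxent")) {
    m <- maxent_model(as.integer(obj$n_neurons), feats, theta,
                      log_z = if (is.null(obj$log_z)) NULL else
                        as.numeric(obj$log_z),
                      z_method = if (is.null(obj$z_method)) "none" else
                        obj$z_method)
    return(m)
  }
  if (identical(obj$model_class, "ri")) {
    return(new_ri_model(as.integer(obj$n_neurons), feats, theta,
                        as.numeric(obj$z_ri), as.numeric(obj$p_min)))
  }
  stop("unknown model_class '", obj$model_class, "' in ", path)
}
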