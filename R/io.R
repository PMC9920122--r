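#' Read a region-of-interest time-series table
#'
#' Reads a TSV or CSV file with a header row of region names and one row per
#' time point, and returns it in the package's internal orientation: regions
#' in rows, time points in columns.
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @param subject_id subject label; defaults to the file name without
#'   extension.
#' @return numeric matrix (regions x time) with region rownames and a
#'   `subject_id` attribute.
#' @export
read_roi_table <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 1L) stop("missing header in ", path, call. = FALSE)
  if (nrow(df) < 1L) {
    stop("empty input: ", path, " has a header but no time points",
         call. = FALSE)
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) |
                     !grepl("^[-+0-9.eE]+$", as.character(df[[j]])))[1]
      stop(sprintf("parse error in %s: non-numeric value in column '%s', row %d",
                   path, names(df)[j], if (is.na(bad)) 1L else bad),
           call. = FALSE)
    }
  }
  if (anyDuplicated(names(df))) {
    stop("duplicated region names in header of ", path, call. = FALSE)
  }
  x <- t(as.matrix(df))
  colnames(x) <- NULL
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  attr(x, "subject_id") <- subject_id
  x
}

#' Write a region time-series table
#'
#' Inverse of [read_roi_table()]: writes one row per time point with a header
#' of region names.
#'
#' @param x numeric matrix, regions x time.
#' @param path output path (`.csv` for comma-separated, else tab).
#' @export
write_roi_table <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as.data.frame(t(x))
  names(df) <- roi_labels(x)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subject-group manifest
#'
#' @param path TSV file with columns `subject_id` and `group`.
#' @return data frame with character columns `subject_id`, `group`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(df))) {
    stop("manifest must have columns subject_id and group", call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id in manifest", call. = FALSE)
  }
  df[, c("subject_id", "group")]
}

#' Read and validate a network-definition config
#'
#' The JSON config maps network names to ordered region lists, with optional
#' homologous left/right pairs and a `reduce` flag requesting bilateral
#' averaging (see [reduce_bilateral()]). Validation enforces unique region
#' names per network, a complete pairing whenever `reduce` is set, and an
#' effective (post-reduction) region count of at most 12 — the practical
#' ceiling of the exact maximum-likelihood fit.
#'
#' @param path JSON file path, or a list already in config shape.
#' @return list of class `network_config`: per network a list with `rois`,
#'   `reduce`, and `bilateral_pairs` (data frame or NULL).
#' @export
read_network_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    path
  }
  if (is.null(cfg$networks) || !length(cfg$networks)) {
    stop("config error: no 'networks' entry", call. = FALSE)
  }
  nets <- lapply(names(cfg$networks), function(name) {
    net <- cfg$networks[[name]]
    rois <- unlist(net$rois)
    if (is.null(rois) || !length(rois)) {
      stop("config error: network ", name, " has no rois", call. = FALSE)
    }
    if (anyDuplicated(rois)) {
      stop("config error: duplicated region names in network ", name,
           call. = FALSE)
    }
    reduce <- isTRUE(net$reduce)
    pairs <- NULL
    if (!is.null(net$bilateral_pairs) && length(net$bilateral_pairs)) {
      pairs <- as_bilateral_pairs(net$bilateral_pairs)
      missing <- setdiff(c(pairs$left, pairs$right), rois)
      if (length(missing)) {
        stop("config error: bilateral pair members not in network ", name,
             ": ", paste(missing, collapse = ", "), call. = FALSE)
      }
    }
    if (reduce) {
      if (is.null(pairs) ||
          !setequal(c(pairs$left, pairs$right), rois)) {
        stop("config error: network ", name,
             " sets reduce but its bilateral pairs do not cover every region",
             call. = FALSE)
      }
      n_eff <- nrow(pairs)
    } else {
      n_eff <- length(rois)
    }
    if (n_eff > 12) {
      stop(sprintf(
        "config error: network %s has %d effective regions; at most 12 are supported by the exact fit (set reduce + bilateral pairs)",
        name, n_eff), call. = FALSE)
    }
    list(name = name, rois = rois, reduce = reduce, bilateral_pairs = pairs,
         n_effective = n_eff)
  })
  names(nets) <- names(cfg$networks)
  structure(list(networks = nets), class = "network_config")
}

#' Bundled resting-state network definitions
#'
#' Loads the package's default network config: the frontoparietal (FPN,
#' 12 regions), salience (SAN, 12 regions) and attention (ATN, 10 regions)
#' resting-state networks with their AAL-atlas region lists in standard node
#' order.
#'
#' @return a `network_config` (see [read_network_config()]).
#' @export
default_network_config <- function() {
  read_network_config(system.file("extdata", "networks.json",
                                  package = "energyscape", mustWork = TRUE))
}

#' Extract one network's regions from a full parcellation table
#'
#' Subsets and reorders the rows of a continuous region x time matrix to the
#' configured node order of one network, applying bilateral left/right
#' averaging when the network's `reduce` flag is set.
#'
#' @param x numeric matrix, regions x time, region rownames.
#' @param config a `network_config` (see [read_network_config()]).
#' @param name network name present in the config.
#' @return numeric matrix with the network's (possibly reduced) regions.
#' @export
select_network <- function(x, config, name) {
  stopifnot(inherits(config, "network_config"))
  net <- config$networks[[name]]
  if (is.null(net)) {
    stop("config error: network '", name, "' is not configured; available: ",
         paste(names(config$networks), collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(x))) {
    stop("series must have region rownames", call. = FALSE)
  }
  missing <- setdiff(net$rois, rownames(x))
  if (length(missing)) {
    stop("config error: region(s) absent from series: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- x[net$rois, , drop = FALSE]
  if (net$reduce) out <- reduce_bilateral(out, net$bilateral_pairs)
  out
}

#' Write a local-minima table as TSV
#'
#' @param landscape an [energy_landscape()] object.
#' @param path output path.
#' @export
write_minima_tsv <- function(landscape, path) {
  utils::write.table(minima_table(landscape), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a signature-screen result table as TSV
#'
#' @param signatures data frame from [extract_signatures()] (or the
#'   `signatures` element of a pipeline report).
#' @param path output path.
#' @export
write_signatures_tsv <- function(signatures, path) {
  utils::write.table(signatures, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
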