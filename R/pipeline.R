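#' Run the full network-wise energy-landscape group comparison
#'
#' Executes the complete analysis on a two-group study: for each configured
#' network, subset (and optionally bilaterally reduce) each subject's region
#' time series, binarize per subject at the per-region time mean, concatenate
#' subjects within each group, fit a pairwise maximum entropy model per group,
#' enumerate the group energy landscapes and their local minima, tally the
#' minima over all networks and both groups into the comparison count M, then
#' fit a per-subject model per network, collect each subject's energies at the
#' candidate states (the union of both groups' minima), and screen them with
#' two-sample t-tests at the Bonferroni-corrected level `alpha / M`. The run
#' is fully deterministic given its inputs.
#'
#' @param series a named list of numeric matrices (regions x time, region
#'   rownames; names are subject ids), or a directory containing one
#'   `<subject_id>.tsv` (or `.csv`) table per subject.
#' @param manifest data frame with columns `subject_id`, `group` (exactly two
#'   groups, at least two subjects each), or path to such a TSV.
#' @param config a `network_config`, config list, or path to a JSON config
#'   (see [read_network_config()]).
#' @param alpha family-wise significance level (default 0.05).
#' @param flavor t-test flavor, `"pooled"` or `"welch"`.
#' @param learning_rate,tolerance,max_iter fit options passed to [pmem()].
#' @param binarized set `TRUE` when the input series are already -1/+1
#'   (binarization is then skipped, not re-applied).
#' @return an object of class `pipeline_report`: list with `networks`
#'   (per-network group landscapes, minima tables and candidate states),
#'   `tally` (minima counts per network and group), `m_total`, `alpha`,
#'   `corrected_alpha`, `signatures` (see [extract_signatures()]), `groups`,
#'   and `provenance` (fit control, group sizes, package version).
#' @export
run_pipeline <- function(series, manifest, config, alpha = 0.05,
                         flavor = c("pooled", "welch"),
                         learning_rate = 0.1, tolerance = 1e-5,
                         max_iter = 50000, binarized = FALSE) {
  flavor <- match.arg(flavor)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!inherits(config, "network_config")) {
    config <- read_network_config(config)
  }
  groups <- factor(manifest$group)
  if (nlevels(groups) != 2L) {
    stop("manifest must define exactly two groups", call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  series <- load_subject_series(series, manifest$subject_id)

  fit_stage <- function(x, what) {
    tryCatch(pmem(x, learning_rate = learning_rate, tolerance = tolerance,
                  max_iter = max_iter),
             error = function(e) {
               stop(what, ": ", conditionMessage(e), call. = FALSE)
             })
  }

  lev <- levels(groups)
  net_names <- names(config$networks)
  networks <- list()
  tally <- data.frame(network = character(), group = character(),
                      n_minima = integer(), stringsAsFactors = FALSE)
  subject_bin <- list()   # [[network]][[subject_id]]

  for (nm in net_names) {
    bins <- lapply(seq_len(nrow(manifest)), function(i) {
      sid <- manifest$subject_id[i]
      xs <- tryCatch(select_network(series[[sid]], config, nm),
                     error = function(e) {
                       stop("network ", nm, ", subject ", sid, ": ",
                            conditionMessage(e), call. = FALSE)
                     })
      if (binarized) {
        check_binary_series(xs, what = paste("series of subject", sid))
        storage.mode(xs) <- "integer"
        xs
      } else {
        tryCatch(binarize(xs), error = function(e) {
          stop("network ", nm, ", subject ", sid, ": ",
               conditionMessage(e), call. = FALSE)
        })
      }
    })
    names(bins) <- manifest$subject_id
    subject_bin[[nm]] <- bins

    group_land <- list()
    minima_by_group <- list()
    for (g in lev) {
      concat <- concatenate_group(bins[manifest$group == g])
      fit <- fit_stage(concat, sprintf("network %s, group %s", nm, g))
      land <- energy_landscape(fit)
      group_land[[g]] <- land
      minima_by_group[[g]] <- minima_table(land)
      tally <- rbind(tally, data.frame(network = nm, group = g,
                                       n_minima = length(land$local_minima),
                                       stringsAsFactors = FALSE))
    }
    candidates <- sort(unique(unlist(
      lapply(group_land, function(l) l$local_minima))))
    networks[[nm]] <- list(
      name = nm,
      n_regions = group_land[[1]]$n_regions,
      roi_names = group_land[[1]]$roi_names,
      landscapes = group_land,
      minima_by_group = minima_by_group,
      candidates = candidates
    )
  }

  m_total <- sum(tally$n_minima)
  corrected_alpha <- bonferroni_threshold(alpha, m_total)

  signatures <- NULL
  for (nm in net_names) {
    cand <- networks[[nm]]$candidates
    if (!length(cand)) next
    energies <- t(vapply(manifest$subject_id, function(sid) {
      fit <- fit_stage(subject_bin[[nm]][[sid]],
                       sprintf("network %s, subject %s", nm, sid))
      energies_all_states(fit$params)[cand]
    }, numeric(length(cand))))
    colnames(energies) <- as.character(cand)
    sig <- extract_signatures(energies, groups, m = m_total, alpha = alpha,
                              flavor = flavor,
                              n_regions = networks[[nm]]$n_regions,
                              network = nm)
    networks[[nm]]$subject_energies <- energies
    signatures <- rbind(signatures, sig)
  }
  if (!is.null(signatures)) {
    signatures <- signatures[order(signatures$p, signatures$network,
                                   signatures$state), , drop = FALSE]
    rownames(signatures) <- NULL
  }

  structure(list(
    networks = networks,
    tally = tally,
    m_total = m_total,
    alpha = alpha,
    corrected_alpha = corrected_alpha,
    signatures = signatures,
    groups = lev,
    provenance = list(
      n_subjects = as.list(table(groups)),
      fit_control = list(learning_rate = learning_rate,
                         tolerance = tolerance, max_iter = max_iter),
      test_flavor = flavor,
      package_version = as.character(utils::packageVersion("energyscape"))
    )
  ), class = "pipeline_report")
}

load_subject_series <- function(series, subject_ids) {
  if (is.character(series) && length(series) == 1L) {
    dir <- series
    series <- lapply(subject_ids, function(sid) {
      for (ext in c(".tsv", ".csv")) {
        p <- file.path(dir, paste0(sid, ext))
        if (file.exists(p)) return(read_roi_table(p, subject_id = sid))
      }
      stop("no table found for subject ", sid, " in ", dir, call. = FALSE)
    })
    names(series) <- subject_ids
  }
  missing <- setdiff(subject_ids, names(series))
  if (length(missing)) {
    stop("series missing for subject(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  series
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Energy-landscape group comparison\n")
  cat(sprintf("  groups: %s (n = %s)\n",
              paste(x$groups, collapse = " vs "),
              paste(unlist(x$provenance$n_subjects), collapse = " vs ")))
  cat(sprintf("  networks: %s\n", paste(names(x$networks), collapse = ", ")))
  cat(sprintf("  local minima tallied over networks and groups: M = %d\n",
              x$m_total))
  cat(sprintf("  Bonferroni-corrected level: %g / %d = %g\n",
              x$alpha, x$m_total, x$corrected_alpha))
  if (is.null(x$signatures) || !nrow(x$signatures)) {
    cat("  no candidate states tested\n")
  } else {
    nsig <- sum(x$signatures$significant)
    cat(sprintf("  significant connectivity signatures: %d of %d tested\n",
                nsig, nrow(x$signatures)))
    if (nsig) {
      print(utils::head(
        x$signatures[x$signatures$significant,
                     c("network", "state", "pattern", "t", "p")], 10),
        row.names = FALSE)
    }
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the tally, the per-network minima tables and candidate states, and
#' the signature screen as a deterministic JSON document (no timestamps), so
#' identical runs produce byte-identical files.
#'
#' @param report a `pipeline_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  nets <- lapply(report$networks, function(net) {
    list(n_regions = net$n_regions,
         roi_names = net$roi_names,
         minima_by_group = net$minima_by_group,
         candidates = net$candidates)
  })
  doc <- list(
    groups = report$groups,
    tally = report$tally,
    m_total = report$m_total,
    alpha = report$alpha,
    corrected_alpha = report$corrected_alpha,
    networks = nets,
    signatures = report$signatures,
    provenance = report$provenance
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
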