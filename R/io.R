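#' Write / read a behavior table as CSV
#'
#' Columns: participant, block, trial, rt_s, confidence, correct, choice,
#' delay_s (plus any derived label columns present).
#'
#' @param table Behavior data.frame as returned by [simulate_behavior()].
#' @param path File path.
#' @return `read_behavior_csv` returns the data.frame with canonical column
#'   names (`rt`, `delay` in seconds).
#' @export
write_behavior_csv <- function(table, path) {
  out <- table
  names(out)[names(out) == "rt"] <- "rt_s"
  names(out)[names(out) == "delay"] <- "delay_s"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "rt_s"] <- "rt"
  names(tab)[names(tab) == "delay_s"] <- "delay"
  tab$correct <- as.logical(tab$correct)
  tab
}

#' Serialize a network specification to YAML
#'
#' @param spec A [network_spec()].
#' @param path File path (.yaml).
#' @return `read_network_yaml` reconstructs the [network_spec()] (shared
#'   default region parameters unless per-region values were stored).
#' @export
write_network_yaml <- function(spec, path) {
  edges_list <- function(e, v) {
    if (!nrow(e)) return(list())
    lapply(seq_len(nrow(e)), function(i)
      list(from = e[i, 1], to = e[i, 2], log_gain = unname(v[i])))
  }
  doc <- list(
    regions = as.list(spec$regions),
    input = lapply(seq_along(spec$input_regions), function(i)
      list(region = spec$input_regions[i], log_gain = unname(spec$logC[i]))),
    forward = edges_list(spec$forward_edges, spec$logA_f),
    backward = edges_list(spec$backward_edges, spec$logA_b),
    region_params = lapply(spec$region_params, function(p)
      list(kappa = as.list(p$kappa), g = as.list(p$g), r = p$r)))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_network_yaml
#' @export
read_network_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  edges <- function(lst) {
    if (!length(lst)) return(NULL)
    do.call(rbind, lapply(lst, function(e) c(e$from, e$to)))
  }
  gains <- function(lst) vapply(lst, function(e) as.numeric(e$log_gain),
                                numeric(1))
  rp <- lapply(doc$region_params, function(p)
    cmc_region_params(kappa = unlist(p$kappa), g = unlist(p$g), r = p$r))
  network_spec(unlist(doc$regions),
               forward_edges = edges(doc$forward),
               backward_edges = edges(doc$backward),
               input_regions = vapply(doc$input, `[[`, character(1), "region"),
               logA_f = if (length(doc$forward)) gains(doc$forward),
               logA_b = if (length(doc$backward)) gains(doc$backward),
               logC = if (length(doc$input)) gains(doc$input),
               region_params = rp)
}

#' Write an evidence matrix (subjects x models) as CSV
#'
#' @param F Subjects x models matrix of free energies.
#' @param path File path.
#' @return `read_evidence_csv` returns the numeric matrix.
#' @export
write_evidence_csv <- function(F, path) {
  utils::write.csv(as.data.frame(F), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_evidence_csv
#' @export
read_evidence_csv <- function(path) {
  as.matrix(utils::read.csv(path))
}
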