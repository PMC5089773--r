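#' Write / read a connectivity matrix as CSV
#'
#' Header row and first column carry the population names; rows are sources,
#' columns targets; negative entries are inhibitory connections.
#'
#' @param gamma named square matrix.
#' @param path CSV file.
#' @return The path (write) or the matrix (read), invisibly / visibly.
#' @export
write_gamma_csv <- function(gamma, path) {
  write.csv(as.data.frame(gamma), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gamma_csv
#' @export
read_gamma_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write / read a full model definition
#'
#' The model file is JSON (or YAML when the path ends in `.yaml`/`.yml`):
#' a list of population records (name, G, g, b, p_mean, p_sigma, sigmoid
#' e0/v0/r) plus the connectivity, either inline (`gamma`) or as a path to
#' a CSV (`gamma_csv`, resolved relative to the model file).
#'
#' @param model a [column_model()].
#' @param path output file (`.json`, `.yaml` or `.yml`).
#' @param gamma_csv optional separate CSV file for the connectivity.
#' @return The path, invisibly.
#' @export
write_model_file <- function(model, path, gamma_csv = NULL) {
  stopifnot(inherits(model, "column_model"))
  rec <- list(
    populations = lapply(model$populations, function(p) {
      list(name = p$name, G = p$G, g = p$g, b = p$b,
           p_mean = p$p_mean, p_sigma = p$p_sigma,
           sigmoid = p$sigmoid[c("e0", "v0", "r")])
    }))
  if (is.null(gamma_csv)) {
    rec$gamma <- unname(apply(model$gamma, 1, as.list))
  } else {
    write_gamma_csv(model$gamma, file.path(dirname(path), gamma_csv))
    rec$gamma_csv <- gamma_csv
  }
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(rec, path)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_model_file
#' @export
read_model_file <- function(path) {
  rec <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  pops <- lapply(rec$populations, function(p) {
    population_spec(p$name, G = p$G, g = p$g, b = p$b,
                    p_mean = p$p_mean, p_sigma = p$p_sigma,
                    sigmoid = sigmoid_params(p$sigmoid$e0, p$sigmoid$v0,
                                             p$sigmoid$r))
  })
  gamma <- if (!is.null(rec$gamma_csv)) {
    read_gamma_csv(file.path(dirname(path), rec$gamma_csv))
  } else {
    do.call(rbind, lapply(rec$gamma, function(row) unlist(row)))
  }
  column_model(pops, gamma)
}
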