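#' Serialize a covariance model to JSON
#'
#' Writes variance spectra, true weights, cross-covariance, true
#' correlation, method, decay exponents and seed provenance to a JSON
#' document that [read_model_json()] restores exactly.
#'
#' @param model a \code{cov_model}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "cov_model"))
  obj <- list(
    sigma_xx = model$sigma_xx, sigma_yy = model$sigma_yy,
    sigma_xy = model$sigma_xy, w_x_true = model$w_x_true,
    w_y_true = model$w_y_true, r_true = model$r_true,
    method = model$method, a_x = model$a_x, a_y = model$a_y,
    seed_info = model$seed_info
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a covariance model from JSON
#'
#' @param path path to a file written by [write_model_json()].
#' @return A \code{cov_model}.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(sigma_xx = as.numeric(obj$sigma_xx),
         sigma_yy = as.numeric(obj$sigma_yy),
         sigma_xy = matrix(as.numeric(obj$sigma_xy),
                           length(obj$sigma_xx), length(obj$sigma_yy)),
         w_x_true = as.numeric(obj$w_x_true),
         w_y_true = as.numeric(obj$w_y_true),
         r_true = obj$r_true, method = obj$method,
         a_x = obj$a_x, a_y = obj$a_y,
         seed_info = obj$seed_info),
    class = "cov_model"
  )
}

#' Write a dataset pair to CSV
#'
#' One row per observation; columns are named after the principal component
#' coordinates of the generating model (\code{x_pc1, ..., y_pc1, ...}).
#'
#' @param pair a \code{dataset_pair}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_dataset_csv <- function(pair, path) {
  stopifnot(inherits(pair, "dataset_pair"))
  d <- cbind(pair$X, pair$Y)
  colnames(d) <- c(paste0("x_pc", seq_len(ncol(pair$X))),
                   paste0("y_pc", seq_len(ncol(pair$Y))))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset pair from CSV
#'
#' @param path path to a file written by [write_dataset_csv()].
#' @return A \code{dataset_pair}.
#' @export
read_dataset_csv <- function(path) {
  d <- as.matrix(utils::read.csv(path))
  is_x <- startsWith(colnames(d), "x_pc")
  structure(
    list(X = d[, is_x, drop = FALSE], Y = d[, !is_x, drop = FALSE],
         n = nrow(d)),
    class = "dataset_pair"
  )
}
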