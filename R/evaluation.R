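# Range-normalised field-reconstruction error metrics (NMAE / NRMSE) and
# ensemble error reports.

#' Normalised mean absolute error
#'
#' `NMAE = 100 * sum(|f_ml - f_gt|) / (n * range)` — the mean absolute
#' node-wise error as a percentage of the field's value range over the
#' full dataset.
#'
#' @param f_ml Predicted/reconstructed field values.
#' @param f_gt Ground-truth field values (same length).
#' @param range Normalising range `max(f) - min(f)` over the full
#'   dataset, in field units (> 0).
#' @return Error in percent.
#' @export
nmae <- function(f_ml, f_gt, range) {
  .check_error_args(f_ml, f_gt, range)
  100 * mean(abs(f_ml - f_gt)) / range
}

#' Normalised root-mean-square error
#'
#' `NRMSE = 100 * sqrt(mean((f_ml - f_gt)^2)) / range`. Always at least
#' as large as the NMAE of the same pair (root-mean-square dominates the
#' mean absolute value).
#'
#' @inheritParams nmae
#' @return Error in percent.
#' @export
nrmse <- function(f_ml, f_gt, range) {
  .check_error_args(f_ml, f_gt, range)
  100 * sqrt(mean((f_ml - f_gt)^2)) / range
}

.check_error_args <- function(f_ml, f_gt, range) {
  if (length(f_ml) != length(f_gt)) stop("field lengths differ")
  if (!is.numeric(range) || length(range) != 1L || range <= 0)
    stop("range must be a single positive number")
  invisible()
}

#' Per-mesh NMAE/NRMSE report for a set of reconstructions
#'
#' Scores each mesh's reconstructed field against its ground truth and
#' aggregates as mean +/- standard deviation. The normalising range is
#' the field's value range over the *full* dataset (training and test
#' meshes together), supplied via `norm_range`; pass the ground-truth
#' matrix of only the scored meshes when no wider ensemble exists.
#'
#' @param gt m x N matrix of ground-truth fields (rows = meshes), with
#'   optional rownames as mesh ids.
#' @param reconstructed m x N matrix of reconstructed fields, same order.
#' @param field Field label (`"pressure"` or `"wss"`), for reporting.
#' @param norm_range Dataset-wide field range. Defaults to
#'   `max(gt) - min(gt)` of the supplied ground truth.
#' @param mesh_ids Optional mesh ids (defaults to rownames of `gt`).
#' @return An `error_report`: list with `per_mesh` (data frame mesh_id,
#'   nmae_pct, nrmse_pct), `mean_nmae`, `sd_nmae`, `mean_nrmse`,
#'   `sd_nrmse`, `field`, `norm_range`.
#' @export
evaluate_test_set <- function(gt, reconstructed, field = "field",
                              norm_range = NULL, mesh_ids = NULL) {
  gt <- as.matrix(gt); reconstructed <- as.matrix(reconstructed)
  if (!all(dim(gt) == dim(reconstructed))) stop("matrix shapes differ")
  if (is.null(mesh_ids)) mesh_ids <- rownames(gt)
  if (is.null(mesh_ids)) mesh_ids <- sprintf("mesh_%d", seq_len(nrow(gt)))
  if (length(mesh_ids) != nrow(gt)) stop("mesh id mismatch")
  if (is.null(norm_range)) norm_range <- max(gt) - min(gt)
  per_nmae <- vapply(seq_len(nrow(gt)), function(i)
    nmae(reconstructed[i, ], gt[i, ], norm_range), 0)
  per_nrmse <- vapply(seq_len(nrow(gt)), function(i)
    nrmse(reconstructed[i, ], gt[i, ], norm_range), 0)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(
    list(per_mesh = data.frame(mesh_id = mesh_ids, nmae_pct = per_nmae,
                               nrmse_pct = per_nrmse),
         mean_nmae = mean(per_nmae), sd_nmae = sd0(per_nmae),
         mean_nrmse = mean(per_nrmse), sd_nrmse = sd0(per_nrmse),
         field = field, norm_range = norm_range),
    class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> [%s] %d mesh(es): NMAE %.2f +/- %.2f %%, NRMSE %.2f +/- %.2f %%\n",
              x$field, nrow(x$per_mesh),
              x$mean_nmae, if (is.na(x$sd_nmae)) 0 else x$sd_nmae,
              x$mean_nrmse, if (is.na(x$sd_nrmse)) 0 else x$sd_nrmse))
  invisible(x)
}

#' Write an error report as CSV
#'
#' One row per mesh plus a `summary` row holding the mean values (the
#' standard deviations are in `sd_nmae_pct`/`sd_nrmse_pct` of that row).
#'
#' @param report An `error_report`.
#' @param path Output file path.
#' @export
write_error_report_csv <- function(report, path) {
  df <- report$per_mesh
  df$field <- report$field
  df$sd_nmae_pct <- NA_real_; df$sd_nrmse_pct <- NA_real_
  df <- rbind(df, data.frame(
    mesh_id = "summary", nmae_pct = report$mean_nmae,
    nrmse_pct = report$mean_nrmse, field = report$field,
    sd_nmae_pct = report$sd_nmae, sd_nrmse_pct = report$sd_nrmse))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
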