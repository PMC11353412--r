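# End-to-end experiments: the worked single-matrix example, the extreme
# well/ill-conditioned subcloud comparison, and the effect of surgery on a
# whole cloud and its inverse cloud.

#' The worked-example 3 x 3 filter
#'
#' A fixed 3 x 3 matrix with entries drawn from N(0, 0.01^2), of the kind
#' used to initialise small convolution filters. It is moderately
#' ill-conditioned (kappa about 85) and is the input of the worked surgery
#' example in [experiment_table3()].
#'
#' @return A 3 x 3 numeric matrix.
#' @examples
#' condition_report(example_filter())
#' @export
example_filter <- function() {
  matrix(c(-0.01960899999, 0.02908008031, -0.01058180258,
           -0.00197698226, 0.00825218894, -0.00468615581,
           -0.01207845485, 0.01378971978, -0.00272469409),
         nrow = 3, byrow = TRUE)
}

#' Default death-binning edges
#'
#' The edge sets used by the experiment tables: eight bins ending in a wide
#' final bin that also collects the capped essential class. `"coarse"`
#' (width 0.2, for 64-point clouds) or `"fine"` (width 0.1, for large
#' clouds).
#'
#' @param which `"coarse"` or `"fine"`.
#' @return Numeric vector of bin edges.
#' @export
default_bin_edges <- function(which = c("coarse", "fine")) {
  which <- match.arg(which)
  if (which == "coarse") c(seq(0, 1.4, by = 0.2), 2.5)
  else c(seq(0, 0.7, by = 0.1), 2.5)
}

.cfg_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # small stable checksum; provenance only, not cryptographic
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(s))) %% 100000019
}

.stamp <- function(result, cfg) {
  cfg$tool_version <- as.character(utils::packageVersion("svdsurgery"))
  attr(result, "config") <- cfg
  attr(result, "config_hash") <- .cfg_hash(cfg)
  result
}

#' Worked single-matrix surgery example
#'
#' Applies the three surgery variants to the fixed filter of
#' [example_filter()] and tabulates spectral norm, inverse norm and
#' condition number before and after: tail replacement with pivot 2,
#' linear-combination replacement of the two lower singular values, and
#' full orthogonalisation. The surgery preserves the norm in every row
#' while shrinking the inverse norm, hence kappa.
#'
#' @param lc_weights weights `(a, b)` of the linear-combination row. The
#'   default `(2/3, 1)` replaces both lower singular values with
#'   `2 sigma_1 / 3 + sigma_2`; the convex variant `c(2/3, 1/3)` is the
#'   other natural choice (see the vignette).
#' @return A data frame with rows `original`, `tail_j2`, `lincomb`,
#'   `orthogonal` and columns `norm`, `inverse_norm`, `kappa`.
#' @examples
#' experiment_table3()
#' @export
experiment_table3 <- function(lc_weights = c(2/3, 1)) {
  B <- example_filter()
  mats <- list(original = B,
               tail_j2 = tail_replace(B, 2),
               lincomb = linear_combination_replace(B, lc_weights, 2),
               orthogonal = orthogonalize(B))
  reps <- lapply(mats, condition_report)
  out <- data.frame(matrix_id = names(mats),
                    norm = vapply(reps, `[[`, 0, "norm"),
                    inverse_norm = vapply(reps, `[[`, 0, "inverse_norm"),
                    kappa = vapply(reps, `[[`, 0, "kappa"),
                    row.names = NULL)
  .stamp(out, list(experiment = "table3", lc_weights = lc_weights))
}

.distance_table <- function(pairs, dims = c(0L, 1L)) {
  rows <- lapply(names(pairs), function(nm) {
    d1 <- pairs[[nm]][[1]]; d2 <- pairs[[nm]][[2]]
    vals <- unlist(lapply(dims, function(dm) c(
      bottleneck = diagram_distance(d1, d2, "bottleneck", dimension = dm),
      wasserstein_q1 = diagram_distance(d1, d2, "wasserstein", q = 1, dimension = dm),
      wasserstein_q2 = diagram_distance(d1, d2, "wasserstein", q = 2, dimension = dm))))
    names(vals) <- paste0(rep(c("bottleneck", "wasserstein_q1", "wasserstein_q2"),
                              length(dims)),
                          "_dim", rep(dims, each = 3))
    c(list(pair = nm), as.list(vals))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Extreme-conditioning comparison experiment
#'
#' Generates a Gaussian cloud, extracts the `k` best-conditioned (X1) and
#' `k` worst-conditioned (X2) members, embeds each subcloud and its
#' member-wise inverse cloud on the unit sphere, and compares their
#' Vietoris-Rips persistence: death-binning tables plus bottleneck and
#' Wasserstein distances for the pairs (X1, X2), (X1^-1, X2^-1),
#' (X1, X1^-1) and (X2, X2^-1). A well-conditioned cloud sits close to its
#' inverse cloud in diagram distance; an ill-conditioned one does not.
#'
#' @param count cloud size.
#' @param k subcloud size.
#' @param seed RNG seed for the cloud.
#' @param edges death-binning edges.
#' @return A list with `kappa_range` (2 x 2: X1/X2 min and max kappa),
#'   `diagrams`, `binning` and `distances`.
#' @export
experiment_extremes <- function(count = 10000L, k = 64L, seed = 1L,
                                edges = default_bin_edges("coarse")) {
  cloud <- generate_gaussian_cloud(count, seed = seed)
  ext <- select_extremes(cloud, k)
  clouds <- list(X1 = ext$bottom, X2 = ext$top)
  clouds$X1_inv <- invert_cloud(clouds$X1)
  clouds$X2_inv <- invert_cloud(clouds$X2)
  diagrams <- lapply(clouds, function(cl)
    rips_persistence(embed_cloud(cl), max_dim = 1L, max_radius = 2.5))
  binning <- lapply(diagrams, death_binning, edges = edges)
  distances <- .distance_table(list(
    "X1 vs X2" = diagrams[c("X1", "X2")],
    "X1_inv vs X2_inv" = diagrams[c("X1_inv", "X2_inv")],
    "X1 vs X1_inv" = diagrams[c("X1", "X1_inv")],
    "X2 vs X2_inv" = diagrams[c("X2", "X2_inv")]))
  kappa_range <- rbind(
    X1 = range(vapply(ext$bottom, function(m) condition_report(m)$kappa, 0)),
    X2 = range(vapply(ext$top, function(m) condition_report(m)$kappa, 0)))
  colnames(kappa_range) <- c("min", "max")
  .stamp(list(kappa_range = kappa_range, diagrams = diagrams,
              binning = binning, distances = distances),
         list(experiment = "x1x2", count = count, k = k, seed = seed,
              edges = edges))
}

#' Whole-cloud surgery experiment
#'
#' Generates a Gaussian cloud, applies two surgeries to every member —
#' tail replacement with pivot 2 (cloud A1) and full orthogonalisation
#' (cloud A2) — and compares the persistence diagram of each embedded
#' cloud with that of its embedded inverse cloud. For the orthogonalised
#' cloud the inverse of each member is its transpose up to scale, so the
#' two embedded clouds are isometric and every diagram distance is zero.
#'
#' Persistence is computed on the first `subsample` members; the surgery
#' itself and the condition-number summaries run on the full cloud.
#'
#' @param count cloud size.
#' @param subsample number of members embedded for persistence.
#' @param seed RNG seed.
#' @param edges death-binning edges.
#' @return A list with `kappa` (per-cloud min/max/mean table), `diagrams`,
#'   `binning` and `distances`.
#' @export
experiment_cloud_surgery <- function(count = 10000L, subsample = 200L,
                                     seed = 1L,
                                     edges = default_bin_edges("fine")) {
  cloud <- generate_gaussian_cloud(count, seed = seed)
  A1 <- apply_policy_batch(cloud, surgery_policy("tail_replace", pivot_j = 2))
  A2 <- apply_policy_batch(cloud, surgery_policy("orthogonalize"))
  kappa_tab <- do.call(rbind, lapply(
    list(A = cloud, A1 = A1, A2 = A2), function(cl)
      condition_summary(cl, bins = 10)$stats[3, c("min", "max", "mean")]))
  kappa_tab <- data.frame(cloud = rownames(kappa_tab), kappa_tab,
                          row.names = NULL)
  sub <- function(cl) new_matrix_cloud(cl[seq_len(min(subsample, length(cl)))],
                                       attr(cl, "provenance"))
  base_clouds <- list(A = sub(cloud), A1 = sub(A1), A2 = sub(A2))
  diagrams <- list()
  for (nm in names(base_clouds)) {
    diagrams[[nm]] <- rips_persistence(embed_cloud(base_clouds[[nm]]),
                                       max_dim = 1L, max_radius = 2.5)
    diagrams[[paste0(nm, "_inv")]] <- rips_persistence(
      embed_cloud(invert_cloud(base_clouds[[nm]]), "inverse"),
      max_dim = 1L, max_radius = 2.5)
  }
  binning <- lapply(diagrams, death_binning, edges = edges)
  distances <- .distance_table(list(
    "A vs A_inv" = diagrams[c("A", "A_inv")],
    "A1 vs A1_inv" = diagrams[c("A1", "A1_inv")],
    "A2 vs A2_inv" = diagrams[c("A2", "A2_inv")]))
  .stamp(list(kappa = kappa_tab, diagrams = diagrams, binning = binning,
              distances = distances),
         list(experiment = "cloud_surgery", count = count,
              subsample = subsample, seed = seed, edges = edges))
}

#' Batch surgery over matrices on disk
#'
#' Reads every delimited-text matrix in `input` (a directory or a single
#' file), applies the policy, writes the post-surgery matrices to
#' `output_dir` under the same file names, and returns (and writes as
#' `report.csv`) the per-matrix before/after condition table.
#'
#' @param input a directory of matrix text files, or one file.
#' @param policy a [surgery_policy()].
#' @param output_dir output directory (created if missing).
#' @param delim field delimiter.
#' @return The report data frame, invisibly-written to
#'   `output_dir/report.csv`.
#' @export
cmd_surgery <- function(input, policy, output_dir, delim = "\t") {
  files <- if (dir.exists(input)) {
    list.files(input, pattern = "\\.(txt|tsv|csv|mat)$", full.names = TRUE)
  } else if (file.exists(input)) input else {
    stop("input not found: ", input, call. = FALSE)
  }
  if (!length(files)) stop("no matrix files in ", input, call. = FALSE)
  mats <- lapply(files, read_matrix_txt, delim = delim)
  cloud <- matrix_cloud(mats)
  out <- apply_policy_batch(cloud, policy)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(out))
    write_matrix_txt(out[[i]], file.path(output_dir, basename(files[i])), delim)
  report <- attr(out, "reports")
  report$file <- basename(files)
  utils::write.csv(report, file.path(output_dir, "report.csv"),
                   row.names = FALSE)
  report
}
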