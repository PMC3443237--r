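#' Write a scan report to disk
#'
#' Emits, under `out_dir`: `clusters.tsv` (every cluster found, columns N,
#' M, centre x/y/z, volume in mm^3, major radius in mm, mean member value,
#' p-value), `regions.tsv` (the recurrent-region collapse of the
#' significant clusters, same columns), `scan.json` (full ellipsoid
#' geometry — centres, axes, radii, members — plus the engine settings and
#' seed for provenance), and `null_radius.csv` (the per-(M, N') significance
#' radius feeding the trade-off heuristic).
#'
#' @param scan a [peakclust()] result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report <- function(scan, out_dir) {
  stopifnot(inherits(scan, "peakclust"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(tab) {
    data.frame(N = tab$N, M = tab$M,
               x = tab$x, y = tab$y, z = tab$z,
               volume_mm3 = tab$volume_mm3,
               major_radius_mm = tab$major_radius_mm,
               mean_value = tab$mean_value,
               p = tab$p)
  }
  p_clusters <- file.path(out_dir, "clusters.tsv")
  write.table(fmt(scan$table), p_clusters, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p_regions <- file.path(out_dir, "regions.tsv")
  write.table(fmt(reported_regions(scan)), p_regions, sep = "\t",
              quote = FALSE, row.names = FALSE)

  ell_json <- lapply(scan$ellipsoids, function(e) list(
    center_mm = e$center_mm,
    axes = e$axes,
    radii_mm = e$radii_mm,
    volume_mm3 = e$volume_mm3,
    n_participants = e$n_participants,
    mean_value = e$mean_value,
    members = e$members))
  p_json <- file.path(out_dir, "scan.json")
  jsonlite::write_json(
    list(settings = list(m_range = range(scan$m_values),
                         n_min = scan$n_min,
                         n_participants = scan$n_participants,
                         perms = scan$perms, alpha = scan$alpha,
                         threshold = scan$threshold,
                         iterations = scan$iterations,
                         restarts = scan$restarts,
                         seed = scan$seed),
         clusters = scan$table,
         ellipsoids = ell_json),
    p_json, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  p_null <- file.path(out_dir, "null_radius.csv")
  nc <- data.frame(M = scan$m_values, scan$null_crit, check.names = FALSE)
  names(nc) <- c("M", paste0("N", scan$n_values))
  write.table(nc, p_null, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(c(p_clusters, p_regions, p_json, p_null))
}
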