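#' Deterministic peak-list fixtures for the clustering layer
#'
#' Emulates the statistical structure the group test assumes, without the
#' MEG simulator: each participant gets `peaks_per_participant` peaks, all
#' but (optionally) one scattered uniformly in a brain-like mm box
#' ("decoys"), plus — in a `participation` fraction of participants — one
#' "true" peak jittered around a common location with isotropic Gaussian
#' SD. The true peak's rank is drawn uniformly from `1:true_rank_max`
#' (values are constructed so the ranking lands there); decoy values are
#' i.i.d. uniform, so under `participation = 0` peak rank carries no
#' spatial information and any detection is a false positive.
#'
#' @param n_participants number of participants.
#' @param peaks_per_participant peaks per list.
#' @param center_mm common true-peak location (mm).
#' @param jitter_sd_mm isotropic SD of the true peak around `center_mm`.
#' @param participation fraction of participants carrying the true peak; a
#'   random subset of size `round(participation * n_participants)` gets it.
#' @param box_mm 3 x 2 matrix of (min, max) mm bounds for decoy locations.
#' @param true_rank_max the planted peak's rank is uniform on
#'   `1:true_rank_max`.
#' @param seed optional integer seed.
#' @return List of [peak_list()] objects. Participants carrying the planted
#'   peak record its index in attribute `"true_index"` (position in rank
#'   order).
#' @export
make_fixture <- function(n_participants = 10, peaks_per_participant = 30,
                         center_mm = c(52, -29, 13), jitter_sd_mm = 5,
                         participation = 1,
                         box_mm = cbind(c(-72, -106, -50), c(72, 72, 80)),
                         true_rank_max = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(participation >= 0, participation <= 1, jitter_sd_mm >= 0,
            peaks_per_participant >= 1)
  n_true <- round(participation * n_participants)
  carriers <- sort(sample.int(n_participants, n_true))
  P <- peaks_per_participant
  lapply(seq_len(n_participants), function(i) {
    has_true <- i %in% carriers
    n_decoy <- P - as.integer(has_true)
    loc <- cbind(runif(n_decoy, box_mm[1, 1], box_mm[1, 2]),
                 runif(n_decoy, box_mm[2, 1], box_mm[2, 2]),
                 runif(n_decoy, box_mm[3, 1], box_mm[3, 2]))
    val <- runif(n_decoy)
    if (has_true) {
      tloc <- center_mm + rnorm(3, 0, jitter_sd_mm)
      r <- sample.int(min(true_rank_max, P), 1)
      # a value strictly between the (r-1)-th and r-th largest decoys
      sv <- sort(val, decreasing = TRUE)
      hi <- if (r == 1) 1 + 1e-3 else sv[r - 1]
      lo <- if (r > n_decoy) 0 else sv[r]
      loc <- rbind(loc, tloc)
      val <- c(val, (hi + lo) / 2)
    }
    pl <- peak_list(sprintf("p%02d", i), loc, val, sign = "positive")
    if (has_true) attr(pl, "true_index") <- which(pl$value == val[P])
    pl
  })
}
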