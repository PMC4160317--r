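# End-to-end pipeline: detect -> track -> link.

#' Run the full detection-tracking-linking pipeline
#'
#' Detects heads in every frame, associates them into tracks with the
#' Kalman/feature-matching tracker, links trajectory fragments and prunes
#' spurious tracks. Deterministic given the frames and configuration.
#'
#' @param frames list of frame matrices, a directory readable by
#'   [readFrames()], or a function `(t) -> matrix` (give `nFrames` too).
#' @param nFrames frame count; required when `frames` is a function.
#' @param config a [PipelineConfig-class].
#' @param outDetections,outTracks,outTrajectories optional CSV paths for the
#'   intermediate and final outputs.
#' @param verbose print per-stage progress.
#' @return list with `detections` (per-frame list), `trackSet`
#'   (a [TrackSet-class], pre-linking), `trajectories` (final table) and
#'   `counts` (per-stage summary counts).
#' @export
runPipeline <- function(frames, config = pipelineConfig(), nFrames = NULL,
                        outDetections = NULL, outTracks = NULL,
                        outTrajectories = NULL, verbose = FALSE) {
  if (is.character(frames)) frames <- readFrames(frames)
  getFrame <- if (is.function(frames)) frames else function(t) frames[[t]]
  if (is.null(nFrames)) {
    if (is.function(frames)) stop("nFrames is required when frames is a function")
    nFrames <- length(frames)
  }
  detections <- vector("list", nFrames)
  for (t in seq_len(nFrames)) {
    detections[[t]] <- detectHeads(getFrame(t), config@detection)
    if (verbose && t %% 50 == 0)
      message("detect: frame ", t, "/", nFrames)
  }
  if (!is.null(outDetections)) writeDetections(detections, outDetections)
  ts <- trackFish(getFrame, detections, tracking = config@tracking,
                  linking = config@linking, nFrames = nFrames, verbose = FALSE)
  if (!is.null(outTracks)) {
    tab <- trackTable(ts)
    write.csv(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
              outTracks, row.names = FALSE, quote = FALSE)
  }
  nRaw <- nTracks(ts)
  traj <- finalTrajectories(ts)
  if (!is.null(outTrajectories)) writeTrajectories(traj, outTrajectories)
  counts <- list(frames = nFrames,
                 detections = sum(vapply(detections, nrow, numeric(1))),
                 rawTracks = nRaw,
                 trajectories = length(unique(traj$traj_id)))
  if (verbose)
    message(sprintf("pipeline: %d detections, %d raw tracks, %d trajectories",
                    counts$detections, counts$rawTracks, counts$trajectories))
  list(detections = detections, trackSet = ts, trajectories = traj,
       counts = counts)
}
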