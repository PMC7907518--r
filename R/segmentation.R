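#' Slice a recording into fixed-length non-overlapping patches
#'
#' Returns `floor(length / (patch_duration_s * rate))` segments ordered by
#' index; the trailing remainder is discarded. A recording shorter than one
#' patch yields an empty list with a warning.
#'
#' @param rec A standardized [audio_recording()].
#' @param patch_duration_s Patch duration in seconds, default 0.96 s.
#' @return List of segments, each a list with `subject_id`, `index`
#'   (0-based), `samples`, `start_time_s`, `label`.
#' @export
extract_patches <- function(rec, patch_duration_s = 0.96) {
  stopifnot(inherits(rec, "audio_recording"))
  if (is.matrix(rec$samples)) {
    stop("recording must be standardized to mono before patch extraction",
         call. = FALSE)
  }
  plen <- round(patch_duration_s * rec$sample_rate_hz)
  n_seg <- length(rec$samples) %/% plen
  if (n_seg == 0L) {
    warning("recording ", rec$subject_id, " shorter than one patch (",
            patch_duration_s, " s); returning no segments", call. = FALSE)
    return(list())
  }
  lapply(seq_len(n_seg) - 1L, function(i) {
    list(subject_id = rec$subject_id, index = i,
         samples = rec$samples[i * plen + seq_len(plen)],
         start_time_s = i * patch_duration_s, label = rec$label)
  })
}

#' Speaker-disjoint stratified train/test split
#'
#' Randomly assigns `train_fraction` of the speakers of each class to the
#' training partition and the rest to the test partition. The split is
#' stratified by label (per-class train size is `round(fraction * n)`),
#' subject-disjoint by construction and deterministic given `seed`.
#'
#' @param manifest Manifest data.frame (see [read_manifest()]).
#' @param train_fraction Fraction of speakers per class in the train set.
#' @param seed Integer seed.
#' @return List with `train` and `test` manifests, `partition` filled in.
#' @export
speaker_partition <- function(manifest, train_fraction = 0.8, seed = 1L) {
  manifest <- validate_manifest(manifest)
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- table(manifest$label)
  if (any(counts < 2L)) {
    stop("each class needs at least 2 subjects to stratify", call. = FALSE)
  }
  train_ids <- with_local_seed(seed, {
    unlist(lapply(split(manifest$subject_id, manifest$label), function(ids) {
      sample(ids, round(train_fraction * length(ids)))
    }), use.names = FALSE)
  })
  manifest$partition <- ifelse(manifest$subject_id %in% train_ids,
                               "train", "test")
  list(train = manifest[manifest$partition == "train", , drop = FALSE],
       test = manifest[manifest$partition == "test", , drop = FALSE])
}
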