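# Parameter profiles and config loading. Profiles D1 (20 fish, strong
# lighting) and D2 (40 fish, ordinary lighting) carry the published
# parameter set for the two zebrafish test groups; "synthetic" matches the
# geometry of the built-in renderer (fish length 60 px, head half-width 8,
# tail half-width 2, so the width threshold sits midway between tail width
# 4 px and head width 16 px).

.profiles <- list(
  D1 = list(tG = 75, tU = 70, tL = 9, tW = 16, omega = 0.5, pcMax = 60,
            dcMax = 180, tO = 300, nFish = 20),
  D2 = list(tG = 40, tU = 40, tL = 7, tW = 9, omega = 0.4, pcMax = 80,
            dcMax = 180, tO = 350, nFish = 40),
  synthetic = list(tG = 75, tU = 25, tL = 9, tW = 10, omega = 0.5,
                   pcMax = 60, dcMax = 180, tO = 300, nFish = 10)
)

.configDefaults <- list(
  nBackgroundFrames = 31, minBlobArea = 30, medianKernel = 3,
  scales = c(2, 3, 4, 6, 8), anisotropyMin = 1.2, darkFish = TRUE
)

#' Build a pipeline configuration
#'
#' Starts from a named profile (\code{"D1"}, \code{"D2"} or
#' \code{"synthetic"}) and applies any overrides given as named arguments.
#'
#' @param profile profile name.
#' @param ... overrides for any \code{\link{FishTrackConfig-class}} slot.
#' @return a validated \code{\link{FishTrackConfig-class}}.
#' @export
#' @examples
#' cfg <- fishTrackConfig("D1")
#' cfg <- fishTrackConfig("synthetic", nFish = 10)
fishTrackConfig <- function(profile = c("D1", "D2", "synthetic"), ...) {
  profile <- match.arg(profile)
  vals <- utils::modifyList(c(.profiles[[profile]], .configDefaults),
                            list(...))
  known <- c(names(.profiles$D1), names(.configDefaults))
  unknown <- setdiff(names(list(...)), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  new("FishTrackConfig",
      tG = vals$tG, nBackgroundFrames = vals$nBackgroundFrames,
      minBlobArea = vals$minBlobArea, medianKernel = vals$medianKernel,
      tU = vals$tU, tL = vals$tL, tW = vals$tW,
      scales = as.numeric(vals$scales), anisotropyMin = vals$anisotropyMin,
      omega = vals$omega, pcMax = vals$pcMax, dcMax = vals$dcMax,
      tO = vals$tO, nFish = vals$nFish,
      darkFish = isTRUE(vals$darkFish))
}

#' Load a configuration from a YAML file
#'
#' The file may name a \code{profile} and override any subset of keys;
#' unspecified keys take the profile defaults and unknown keys are
#' rejected with an error naming the key. An empty file yields the pure
#' profile.
#'
#' @param path YAML file path.
#' @param profile default profile when the file names none.
#' @return a validated \code{\link{FishTrackConfig-class}}.
#' @export
loadConfig <- function(path, profile = "D1") {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("malformed config file: ", path)
  if (!is.null(vals$profile)) {
    profile <- vals$profile
    vals$profile <- NULL
  }
  if (!profile %in% names(.profiles))
    stop("unknown profile: ", profile)
  do.call(fishTrackConfig, c(list(profile = profile), vals))
}
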