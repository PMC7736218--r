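.montageCache <- new.env(parent = emptyenv())

#' Standard 64-channel 10/20 montage
#'
#' Returns the packaged 64-channel extended 10/20 montage with approximate
#' 2-D head-surface coordinates (x: left negative to right positive;
#' y: posterior negative to anterior positive). Used by the synthetic-EEG
#' generator for the spatial profile of the right-frontal source and by the
#' spatial-filter topography scoring.
#'
#' @return data.frame with columns \code{label}, \code{x}, \code{y}.
#' @examples
#' head(standardMontage64())
#' @export
standardMontage64 <- function() {
  if (is.null(.montageCache$m)) {
    path <- system.file("extdata", "montage_10_20_64.tsv",
                        package = "stopBeta", mustWork = TRUE)
    .montageCache$m <- utils::read.table(path, header = TRUE, sep = "\t",
                                         stringsAsFactors = FALSE)
  }
  .montageCache$m
}

#' Right-frontal and frontal regions of interest
#'
#' Channel label sets used to score whether a spatial-filter topography is
#' right-frontal (primary criterion) or frontal (fallback criterion).
#'
#' @param which "right_frontal" or "frontal".
#' @return character vector of channel labels.
#' @export
montageRoi <- function(which = c("right_frontal", "frontal")) {
  which <- match.arg(which)
  switch(which,
    right_frontal = c("AF4", "F4", "F6", "F8", "FC4", "FC6", "FT8"),
    frontal = c("AFz", "Fz", "F1", "F2", "F3", "F4", "F5", "F6", "F7", "F8"))
}
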