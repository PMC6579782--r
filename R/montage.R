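# Approximate 10-20 electrode directions as (inclination from vertex,
# azimuth from nose, degrees); left hemisphere has positive azimuth.
# Only relative geometry matters here (re-referencing and inverse-distance
# interpolation), so idealized spherical angles are used.
.montageAngles <- rbind(
  Fp1 = c(90,  18), Fp2 = c(90, -18),
  F7  = c(90,  54), F3  = c(60,  39), Fz = c(45,    0),
  F4  = c(60, -39), F8  = c(90, -54),
  T7  = c(90,  90), C3  = c(45,  90), Cz = c(0,     0),
  C4  = c(45, -90), T8  = c(90, -90),
  P7  = c(90, 126), P3  = c(60, 141), Pz = c(45,  180),
  P4  = c(60, -141), P8 = c(90, -126),
  O1  = c(90, 162), Oz  = c(90, 180), O2 = c(90, -162),
  M1  = c(115, 100), M2 = c(115, -100))

#' Construct a Montage
#'
#' @param channelNames unique channel labels.
#' @param positions channels x 3 matrix of unit-norm xyz coordinates.
#' @param mastoidLabels length-2 character vector naming the mastoid
#'   reference channels (must be montage channels).
#' @return a [Montage-class] object.
#' @export
montage <- function(channelNames, positions, mastoidLabels) {
  positions <- as.matrix(positions)
  rownames(positions) <- channelNames
  colnames(positions) <- c("x", "y", "z")
  new("Montage", channelNames = as.character(channelNames),
      positions = positions, mastoidLabels = as.character(mastoidLabels))
}

#' Standard 10-20 montage
#'
#' A 22-channel montage: the 20 scalp electrodes of the classic 10-20 layout
#' plus left/right mastoids (M1, M2) used for offline re-referencing.
#' Positions are idealized unit-sphere coordinates (nose +x, left ear +y,
#' vertex +z).
#'
#' @return a [Montage-class] with mastoids \code{M1}/\code{M2}.
#' @examples
#' m <- standardMontage()
#' channelNames(m)
#' @export
standardMontage <- function() {
  ang <- .montageAngles * pi / 180
  pos <- cbind(sin(ang[, 1]) * cos(ang[, 2]),
               sin(ang[, 1]) * sin(ang[, 2]),
               cos(ang[, 1]))
  colnames(pos) <- c("x", "y", "z")
  montage(rownames(.montageAngles), pos, c("M1", "M2"))
}

#' Subset a montage to a set of channels
#'
#' @param m a [Montage-class].
#' @param channels channel labels to keep; must include both mastoids if the
#'   result is to be re-referenced.
#' @param mastoidLabels mastoid pair of the subset (defaults to the original
#'   pair when both are kept).
#' @return a [Montage-class] restricted to \code{channels}.
#' @export
subsetMontage <- function(m, channels, mastoidLabels = NULL) {
  stopifnot(is(m, "Montage"))
  missing <- setdiff(channels, m@channelNames)
  if (length(missing))
    stop("unknown channels: ", paste(missing, collapse = ", "))
  if (is.null(mastoidLabels)) {
    if (!all(m@mastoidLabels %in% channels))
      stop("subset drops a mastoid; supply mastoidLabels explicitly")
    mastoidLabels <- m@mastoidLabels
  }
  montage(channels, m@positions[channels, , drop = FALSE], mastoidLabels)
}

#' Scalp (non-mastoid) channels of a montage
#'
#' @param m a [Montage-class].
#' @return channel labels excluding the mastoid pair. These are the channels
#'   that enter artifact rejection, interpolation and the PLV network.
#' @export
scalpChannels <- function(m) {
  stopifnot(is(m, "Montage"))
  setdiff(m@channelNames, m@mastoidLabels)
}

#' Write / read a montage as a JSON sidecar
#'
#' The sidecar maps channel names to xyz coordinates and records the mastoid
#' pair, so EDF exports can travel with their geometry.
#'
#' @param m a [Montage-class].
#' @param path file path of the JSON sidecar.
#' @return \code{readMontageJSON} returns a [Montage-class];
#'   \code{writeMontageJSON} returns \code{path} invisibly.
#' @export
writeMontageJSON <- function(m, path) {
  stopifnot(is(m, "Montage"))
  pos <- lapply(seq_along(m@channelNames), function(i)
    as.numeric(m@positions[i, ]))
  names(pos) <- m@channelNames
  jsonlite::write_json(list(channels = pos, mastoids = m@mastoidLabels),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname writeMontageJSON
#' @export
readMontageJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- do.call(rbind, j$channels)
  montage(names(j$channels), pos, j$mastoids)
}
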