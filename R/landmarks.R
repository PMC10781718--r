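# Anatomical landmark sets and the lateral-cephalogram prognathism rule.

.tmj_landmark_names <- c("N", "OrR", "OrL", "PoR", "PoL", "Ba", "Cg",
                         "EmR", "EmL", "GfR", "GfL")

#' Craniofacial landmark set
#'
#' The eleven named reference points used to build the reference frame:
#' nasion (N), right/left orbitale (OrR/OrL), right/left porion (PoR/PoL),
#' basion (Ba), crista galli (Cg), right/left lateral lip of the articular
#' eminence (EmR/EmL) and right/left glenoid fossa apex (GfR/GfL).
#'
#' @param ... Named xyz triples (mm), or a single named list of them; exactly
#'   the eleven names above must be present.
#' @return Object of class `tmj_landmarks`: a named list of xyz points.
#' @export
landmark_set <- function(...) {
  pts <- list(...)
  if (length(pts) == 1L && is.list(pts[[1]]) && is.null(names(pts)[1])) {
    pts <- pts[[1]]
  }
  miss <- setdiff(.tmj_landmark_names, names(pts))
  extra <- setdiff(names(pts), .tmj_landmark_names)
  if (length(miss)) {
    stop("missing landmarks: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(extra)) {
    stop("unknown landmarks: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  pts <- lapply(pts[.tmj_landmark_names], .as_point3)
  for (pair in list(c("OrR", "OrL"), c("PoR", "PoL"),
                    c("EmR", "EmL"), c("GfR", "GfL"))) {
    if (.norm3(pts[[pair[1]]] - pts[[pair[2]]]) < .tmj_tol$geom) {
      stop(sprintf("degenerate geometry: %s/%s coincide", pair[1], pair[2]),
           call. = FALSE)
    }
  }
  structure(pts, class = "tmj_landmarks")
}

#' Coordinates of a landmark set as a matrix
#' @param lm A [landmark_set()].
#' @param names Which landmarks (default all eleven).
#' @return n x 3 matrix with rownames.
#' @export
landmark_matrix <- function(lm, names = .tmj_landmark_names) {
  stopifnot(inherits(lm, "tmj_landmarks"))
  m <- do.call(rbind, lapply(names, function(nm) lm[[nm]]))
  rownames(m) <- names
  m
}

#' Transform a landmark set rigidly
#' @param lm A [landmark_set()].
#' @param tf A [rigid_transform()].
#' @return The transformed [landmark_set()].
#' @export
transform_landmarks <- function(lm, tf) {
  landmark_set(lapply(unclass(lm), function(p) apply_rigid(tf, p)))
}

#' Read landmarks from JSON
#'
#' Strict reader for `{"name": [x, y, z], ...}` files holding exactly the
#' eleven reference-point names.
#'
#' @param path JSON file path.
#' @return A [landmark_set()].
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(lapply(obj, as.numeric))
}

#' Write landmarks to JSON
#' @param lm A [landmark_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_json <- function(lm, path) {
  stopifnot(inherits(lm, "tmj_landmarks"))
  jsonlite::write_json(lapply(unclass(lm), unname), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Lateral-cephalogram landmarks
#'
#' 2D points (mm) on a lateral cephalogram, for the mandibular-prognathism
#' screening rule.
#'
#' @param porion,orbitale,nasion,pogonion Numeric xy pairs (mm).
#' @return Object of class `tmj_ceph`.
#' @export
ceph_landmarks <- function(porion, orbitale, nasion, pogonion) {
  as2 <- function(p, what) {
    p <- as.numeric(p)
    if (length(p) != 2L || !all(is.finite(p))) {
      stop(sprintf("'%s' must be a finite numeric xy pair", what),
           call. = FALSE)
    }
    p
  }
  out <- list(porion = as2(porion, "porion"),
              orbitale = as2(orbitale, "orbitale"),
              nasion = as2(nasion, "nasion"),
              pogonion = as2(pogonion, "pogonion"))
  if (sqrt(sum((out$porion - out$orbitale)^2)) < .tmj_tol$geom) {
    stop("degenerate geometry: porion and orbitale coincide", call. = FALSE)
  }
  structure(out, class = "tmj_ceph")
}

#' Mandibular prognathism rule on a lateral cephalogram
#'
#' The Frankfort horizontal (FH) line runs through porion and orbitale; the
#' vertical reference is the perpendicular to FH through nasion
#' (N-perpendicular). The rule classifies prognathism when the pogonion lies
#' strictly more than 1 mm anterior to the N-perpendicular, where "anterior"
#' is the porion-to-orbitale direction along FH.
#'
#' @param ceph A [ceph_landmarks()] object.
#' @param threshold_mm Anterior distance beyond which prognathism is called
#'   (strict inequality); default 1 mm.
#' @return List with `distance_mm` (signed anterior distance of pogonion from
#'   the N-perpendicular) and `prognathism` (logical).
#' @export
diagnose_prognathism <- function(ceph, threshold_mm = 1) {
  stopifnot(inherits(ceph, "tmj_ceph"))
  fh <- ceph$orbitale - ceph$porion
  u <- fh / sqrt(sum(fh^2))    # anterior unit direction along FH
  d <- sum((ceph$pogonion - ceph$nasion) * u)
  list(distance_mm = d, prognathism = d > threshold_mm)
}
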