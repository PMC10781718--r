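# The landmark-derived reference frame: MAP, MSP, COP, per-side EmP, GfSP,
# GfCP, plus anatomical direction conventions.

#' Build the craniofacial reference frame from landmarks
#'
#' Constructs the eight reference planes:
#' * MAP (mid-axial): through OrR, OrL and PoR;
#' * MSP (mid-sagittal): perpendicular to MAP, through Cg and Ba;
#' * COP (coronal): perpendicular to MAP and MSP, through Ba;
#' * EmP per side: parallel to MAP through Em of that side;
#' * GfSP per side: parallel to MSP through Gf of that side;
#' * GfCP per side: parallel to COP through Gf of that side.
#'
#' Direction conventions (the source anatomy leaves the plane normals' signs
#' free, so they are fixed by unambiguous anchors): `superior` is the MAP
#' normal oriented toward Cg, `anterior` the COP normal oriented toward N,
#' and `lateral_R`/`lateral_L` the GfSP normal oriented from MSP toward the
#' side's Gf. All stored plane normals are re-oriented to these conventions
#' (EmP normal = superior; GfCP normal = anterior; GfSP normal = lateral of
#' its side). A runtime check asserts that each side's Em lies anterior to
#' its GfCP, consistent with the articular eminence sitting anterior to the
#' fossa.
#'
#' @param landmarks A [landmark_set()].
#' @return Object of class `tmj_frame`: planes `MAP`, `MSP`, `COP`,
#'   `EmP_R`, `EmP_L`, `GfSP_R`, `GfSP_L`, `GfCP_R`, `GfCP_L`; unit vectors
#'   `superior`, `anterior`, `lateral_R`, `lateral_L`.
#' @export
build_reference_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "tmj_landmarks"))
  lm <- landmarks
  with_names <- function(expr, names) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s [landmarks: %s]", conditionMessage(e), names),
           call. = FALSE)
    })
  }
  MAP <- with_names(plane_from_three_points(lm$OrR, lm$OrL, lm$PoR),
                    "OrR/OrL/PoR")
  # superior: MAP normal oriented toward crista galli
  sup <- MAP$normal * sign(signed_distance(MAP, lm$Cg))
  if (abs(signed_distance(MAP, lm$Cg)) < .tmj_tol$geom) {
    stop("degenerate geometry: Cg lies on MAP, superior direction undefined [landmarks: Cg]",
         call. = FALSE)
  }
  MAP <- plane(sup, MAP$point)
  MSP <- with_names(plane_perpendicular_through_line(MAP, lm$Cg, lm$Ba),
                    "Cg/Ba")
  COP <- with_names(plane_perpendicular_to_two(MAP, MSP, lm$Ba), "Ba")
  ant <- COP$normal * sign(signed_distance(COP, lm$N))
  if (abs(signed_distance(COP, lm$N)) < .tmj_tol$geom) {
    stop("degenerate geometry: N lies on COP, anterior direction undefined [landmarks: N]",
         call. = FALSE)
  }
  COP <- plane(ant, COP$point)

  side_planes <- function(side) {
    Em <- lm[[paste0("Em", side)]]
    Gf <- lm[[paste0("Gf", side)]]
    dl <- signed_distance(MSP, Gf)
    if (abs(dl) < .tmj_tol$geom) {
      stop(sprintf("degenerate geometry: Gf%s lies on MSP [landmarks: Gf%s]",
                   side, side), call. = FALSE)
    }
    lat <- MSP$normal * sign(dl)
    list(EmP = plane(MAP$normal, Em),
         GfSP = plane(lat, Gf),
         GfCP = plane(COP$normal, Gf),
         lateral = lat)
  }
  R <- side_planes("R")
  L <- side_planes("L")

  # right and left landmarks must fall on opposite sides of MSP
  if (sign(signed_distance(MSP, lm$GfR)) ==
      sign(signed_distance(MSP, lm$GfL))) {
    stop("GfR and GfL lie on the same side of the mid-sagittal plane",
         call. = FALSE)
  }
  # the articular eminence is anterior to the fossa
  for (side in c("R", "L")) {
    pl <- if (side == "R") R else L
    if (signed_distance(pl$GfCP, lm[[paste0("Em", side)]]) <= 0) {
      warning(sprintf("Em%s is not anterior to GfCP%s; check landmark placement",
                      side, side))
    }
  }
  structure(list(MAP = MAP, MSP = MSP, COP = COP,
                 EmP_R = R$EmP, EmP_L = L$EmP,
                 GfSP_R = R$GfSP, GfSP_L = L$GfSP,
                 GfCP_R = R$GfCP, GfCP_L = L$GfCP,
                 superior = MAP$normal, anterior = COP$normal,
                 lateral_R = R$lateral, lateral_L = L$lateral),
            class = "tmj_frame")
}

#' @export
print.tmj_frame <- function(x, ...) {
  cat("<reference frame>\n")
  for (nm in c("MAP", "MSP", "COP")) {
    n <- x[[nm]]$normal
    cat(sprintf("  %-6s n = (% .4f, % .4f, % .4f)\n", nm, n[1], n[2], n[3]))
  }
  cat(sprintf("  superior (% .3f, % .3f, % .3f), anterior (% .3f, % .3f, % .3f)\n",
              x$superior[1], x$superior[2], x$superior[3],
              x$anterior[1], x$anterior[2], x$anterior[3]))
  invisible(x)
}

# frame planes for one side, as a compact list
.frame_side <- function(frame, side) {
  side <- match.arg(side, c("R", "L"))
  list(EmP = frame[[paste0("EmP_", side)]],
       GfSP = frame[[paste0("GfSP_", side)]],
       GfCP = frame[[paste0("GfCP_", side)]],
       lateral = frame[[paste0("lateral_", side)]])
}

#' Export a reference frame to JSON
#'
#' Emits all plane parameters (unit normal + point) and the direction
#' vectors, so downstream tools can reuse the frame.
#'
#' @param frame A [build_reference_frame()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_frame_json <- function(frame, path) {
  stopifnot(inherits(frame, "tmj_frame"))
  enc <- function(x) {
    if (inherits(x, "tmj_plane")) {
      list(normal = unname(x$normal), point = unname(x$point))
    } else unname(x)
  }
  jsonlite::write_json(lapply(unclass(frame), enc), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
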