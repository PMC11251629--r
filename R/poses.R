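#' Default pose library
#'
#' Eight default hand/wrist/forearm poses plus the neutral `"default"` pose
#' (all joint angles zero): hand `open`/`grasp`, wrist `flex`/`ext`
#' (flexion/extension), `rdev`/`udev` (radial/ulnar deviation) and forearm
#' `pron`/`sup` (pronation/supination). Each pose touches only the degrees
#' of freedom relevant to it; absent DoFs are implicitly zero.
#'
#' Poses can be combined by name with `+`, e.g. `"open+flex"`; the angle maps
#' of the combined poses are summed key-wise (see [resolve_pose()]).
#'
#' @param config configuration list, see [default_config()].
#' @return named list of pose definitions; each is a list with `name` and
#'   `angle_map` (named numeric vector, degrees).
#' @export
load_pose_library <- function(config = default_config()) {
  mcp <- paste0("mcp", 2:5, "_flexion")
  pip <- paste0("pip", 2:5, "_flexion")
  dip <- paste0("dip", 2:5, "_flexion")
  pose <- function(name, ...) {
    am <- c(...)
    stopifnot(all(names(am) %in% config$dof$names))
    list(name = name, angle_map = am)
  }
  vec <- function(nms, val) stats::setNames(rep(val, length(nms)), nms)
  list(
    default = pose("default", stats::setNames(numeric(0), character(0))),
    open  = pose("open", vec(mcp, -30), vec(pip, -10), c(mp1_flexion = -15)),
    grasp = pose("grasp", vec(mcp, 70), vec(pip, 70), vec(dip, 40),
                 c(mp1_flexion = 40, ip1_flexion = 40)),
    flex  = pose("flex", c(wrist_flexion = 60)),
    ext   = pose("ext", c(wrist_flexion = -60)),
    rdev  = pose("rdev", c(wrist_deviation = -20)),
    udev  = pose("udev", c(wrist_deviation = 30)),
    pron  = pose("pron", c(pronation_supination = 80)),
    sup   = pose("sup", c(pronation_supination = -80))
  )
}

#' Resolve a (possibly combined) pose name to a full angle vector
#'
#' `"a+b"` sums the angle maps of poses `a` and `b` key-wise; any number of
#' `+`-separated components is allowed.
#'
#' @param name pose name, possibly combined with `+`.
#' @param library pose library from [load_pose_library()].
#' @param config configuration list.
#' @return named numeric vector of angles (degrees) over the full DoF schema.
#' @export
resolve_pose <- function(name, library = load_pose_library(config),
                         config = default_config()) {
  parts <- strsplit(name, "+", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  angles <- stats::setNames(numeric(length(config$dof$names)),
                            config$dof$names)
  for (p in parts) {
    if (!p %in% names(library)) {
      stop("unknown pose: '", p, "'", call. = FALSE)
    }
    am <- library[[p]]$angle_map
    if (length(am)) angles[names(am)] <- angles[names(am)] + am
  }
  angles
}
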