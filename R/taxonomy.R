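#' @useDynLib shscontext, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median qnorm rnorm runif sd setNames
#' @importFrom utils read.csv write.csv head
NULL

# Canonical joint tables. Ordering within a group is radial-to-ulnar and
# groups are ordered PIP(-IP), MCP, CMC(-M), Wrist; this order fixes the
# input-slot assignment of the grouped (MIMO) classifiers.
.erosion_joints <- data.frame(
  name  = c("ip1", "pip2", "pip3", "pip4", "pip5",
            "mcp1", "mcp2", "mcp3", "mcp4", "mcp5",
            "cmc1", "multangular",
            "navicular", "lunate", "radius", "ulna"),
  group = c(rep("PIP-IP", 5), rep("MCP", 5), rep("CMC-M", 2), rep("Wrist", 4)),
  stringsAsFactors = FALSE
)

.jsn_joints <- data.frame(
  name  = c("pip2", "pip3", "pip4", "pip5",
            "mcp1", "mcp2", "mcp3", "mcp4", "mcp5",
            "cmc3", "cmc4", "cmc5",
            "multangular_navicular", "capitate_navicular_lunate", "radiocarpal"),
  group = c(rep("PIP", 4), rep("MCP", 5), rep("CMC", 3), rep("Wrist", 3)),
  stringsAsFactors = FALSE
)

.assessments <- c("erosion", "jsn")

check_assessment <- function(assessment) {
  if (length(assessment) != 1L || !assessment %in% .assessments) {
    stop("unknown assessment: must be one of ",
         paste(.assessments, collapse = ", "), call. = FALSE)
  }
  assessment
}

check_side <- function(side) {
  if (length(side) != 1L || !side %in% c("left", "right")) {
    stop("side must be 'left' or 'right'", call. = FALSE)
  }
  side
}

#' Target joints of one assessment for one hand
#'
#' Returns the scored joint sites of the modified Sharp/van der Heijde (SHS)
#' system: 16 joints per hand for erosion (the 4 PIP joints, the thumb IP,
#' the 5 MCP joints, the thumb CMC, the multangular, the navicular, the
#' lunate, the radius and the ulna) and 15 for joint space narrowing (the 4
#' PIP joints, the 5 MCP joints, 3 CMC joints, the multangular-navicular,
#' the capitate-navicular-lunate and the radiocarpal joint).
#'
#' @param assessment `"erosion"` or `"jsn"`.
#' @param side `"left"` or `"right"`.
#' @return A data frame with columns `joint_id`, `assessment`, `name`,
#'   `side`, `group` and `order`, in the canonical (radial-to-ulnar within
#'   group) order used for classifier input slots.
#' @export
#' @examples
#' nrow(target_joints("erosion", "right"))  # 16
#' nrow(target_joints("jsn", "left"))       # 15
target_joints <- function(assessment, side = "right") {
  check_assessment(assessment)
  check_side(side)
  tab <- if (assessment == "erosion") .erosion_joints else .jsn_joints
  data.frame(
    joint_id   = paste(assessment, tab$name, side, sep = "."),
    assessment = assessment,
    name       = tab$name,
    side       = side,
    group      = tab$group,
    order      = seq_len(nrow(tab)),
    stringsAsFactors = FALSE
  )
}

#' Full joint taxonomy table
#'
#' Both assessments, both sides: 62 rows (2 x 16 erosion + 2 x 15 JSN).
#' @return A data frame as in [target_joints()].
#' @export
taxonomy_table <- function() {
  do.call(rbind, lapply(.assessments, function(a) {
    rbind(target_joints(a, "right"), target_joints(a, "left"))
  }))
}

#' Joint group of a joint
#'
#' Every joint belongs to exactly one group: for erosion PIP-IP (5), MCP (5),
#' CMC-M (2: thumb CMC and multangular) or Wrist (4: navicular, lunate,
#' radius, ulna); for JSN PIP (4), MCP (5), CMC (3) or Wrist (3).
#'
#' @param assessment `"erosion"` or `"jsn"`.
#' @param name Joint site name(s), e.g. `"mcp3"`.
#' @return Character vector of group names.
#' @export
joint_group <- function(assessment, name) {
  check_assessment(assessment)
  tab <- if (assessment == "erosion") .erosion_joints else .jsn_joints
  idx <- match(name, tab$name)
  if (anyNA(idx)) {
    stop("unknown ", assessment, " joint name: ",
         paste(name[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  tab$group[idx]
}

#' Member joints of a group
#' @param assessment `"erosion"` or `"jsn"`.
#' @param group Group name (e.g. `"Wrist"`).
#' @param side `"left"` or `"right"`.
#' @return Data frame of member joints in canonical order.
#' @export
group_members <- function(assessment, group, side = "right") {
  tj <- target_joints(assessment, side)
  out <- tj[tj$group == group, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("unknown ", assessment, " group: ", group, call. = FALSE)
  }
  out
}

#' Contralateral joint
#'
#' The same anatomical joint on the opposite hand. Applying twice returns
#' the original id; the group never changes.
#'
#' @param joint_id Joint id string(s) of the form
#'   `"<assessment>.<name>.<side>"`, e.g. `"erosion.mcp2.right"`.
#' @return Joint id string(s) with the side flipped.
#' @export
contralateral <- function(joint_id) {
  parts <- strsplit(joint_id, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 3L) stop("malformed joint id", call. = FALSE)
    check_assessment(p[1])
    joint_group(p[1], p[2])  # validates the name
    side <- check_side(p[3])
    paste(p[1], p[2], if (side == "right") "left" else "right", sep = ".")
  }, character(1))
}

#' Grade scale of an assessment
#'
#' SHS erosion is graded 0--5 per joint, joint space narrowing 0--4.
#' @param assessment `"erosion"` or `"jsn"`.
#' @return Integer vector of valid grades.
#' @export
grade_scale <- function(assessment) {
  check_assessment(assessment)
  if (assessment == "erosion") 0:5 else 0:4
}

#' Binarize an SHS grade
#'
#' The binary reading used throughout: grade 0 is `"intact"`, any grade of 1
#' or more is `"non-intact"`.
#'
#' @param grade Integer grade(s) within the assessment's scale.
#' @param assessment `"erosion"` or `"jsn"`.
#' @return Character vector of `"intact"` / `"non-intact"`.
#' @export
#' @examples
#' binarize_grade(0, "erosion")  # "intact"
#' binarize_grade(1, "jsn")      # "non-intact"
binarize_grade <- function(grade, assessment) {
  scale <- grade_scale(assessment)
  bad <- !(grade %in% scale)
  if (any(bad)) {
    stop("grade outside the ", assessment, " scale (",
         min(scale), "-", max(scale), "): ",
         paste(unique(grade[bad]), collapse = ", "), call. = FALSE)
  }
  ifelse(grade == 0, "intact", "non-intact")
}

#' Evaluation box size for a joint
#'
#' Width x height (pixels, at scale-normalized resolution) of the bounding
#' box used both to judge a detection correct and to crop the joint window:
#' 250 x 250 for the PIP, IP, MCP and CMC-M joints, 500 x 300 for the
#' radius, 300 x 300 for all others.
#'
#' @param name Joint site name.
#' @return Named numeric vector `c(width=, height=)`.
#' @export
joint_box <- function(name) {
  stopifnot(length(name) == 1L)
  small <- c("ip1", "pip2", "pip3", "pip4", "pip5",
             "mcp1", "mcp2", "mcp3", "mcp4", "mcp5",
             "cmc1", "multangular")
  if (name %in% small) return(c(width = 250, height = 250))
  if (name == "radius") return(c(width = 500, height = 300))
  all_names <- unique(c(.erosion_joints$name, .jsn_joints$name))
  if (!name %in% all_names) stop("unknown joint name: ", name, call. = FALSE)
  c(width = 300, height = 300)
}

#' Write or read the taxonomy as JSON
#'
#' The full 62-row taxonomy (id, assessment, name, side, group, order) in a
#' machine-readable form; a copy ships with the package under
#' `inst/extdata/shs_taxonomy.json`.
#'
#' @param path File path.
#' @return `write_taxonomy_json()` returns `path` invisibly;
#'   `read_taxonomy_json()` returns the taxonomy data frame.
#' @export
write_taxonomy_json <- function(path) {
  jsonlite::write_json(taxonomy_table(), path, dataframe = "rows",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_taxonomy_json
#' @export
read_taxonomy_json <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Short stable hash of the taxonomy, stored in model checkpoints so a model
# is never applied under a different joint ordering.
taxonomy_hash <- function() {
  tab <- taxonomy_table()
  s <- paste(tab$joint_id, tab$order, collapse = ";")
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%x", h)
}
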