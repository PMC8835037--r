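#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames
#' @importFrom utils read.csv write.table
NULL

GRID_ROLES <- c("self_now", "self_year", "ideal_self", "other")

#' Construct a repertory grid
#'
#' A repertory grid is a matrix of integer ratings (1--7) of elements
#' (Self-Now, Ideal-Self, significant others, roles) on bipolar personal
#' constructs. Rating 1 means "very" like the left pole, 4 is the midpoint
#' (neither pole), and 7 means "very" like the right pole, with 2/3 and 5/6
#' the intermediate "quite"/"slightly" steps.
#'
#' @param constructs data frame with columns `left_pole`, `right_pole` and
#'   (optionally) logical `predefined`; one row per construct.
#' @param elements data frame with columns `label` and `role`; `role` is one
#'   of `"self_now"`, `"self_year"`, `"ideal_self"`, `"other"`. Roles
#'   `self_now` and `ideal_self` must occur exactly once, `self_year` at most
#'   once.
#' @param ratings integer matrix, constructs in rows, elements in columns,
#'   every cell in 1..7.
#' @return An object of class `repgrid`: a list with components
#'   `constructs`, `elements` and `ratings`.
#' @seealso [read_repgrid()], [healthy_habits_template()], [validate_case()]
#' @export
#' @examples
#' g <- repgrid(
#'   data.frame(left_pole = "overweight", right_pole = "correct weight"),
#'   data.frame(label = c("self now", "ideal"),
#'              role = c("self_now", "ideal_self")),
#'   matrix(c(1L, 7L), nrow = 1)
#' )
#' g
repgrid <- function(constructs, elements, ratings) {
  g <- new_repgrid(constructs, elements, ratings)
  problems <- check_repgrid(g)
  if (length(problems)) {
    stop("invalid repertory grid:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  g
}

new_repgrid <- function(constructs, elements, ratings) {
  constructs <- as.data.frame(constructs, stringsAsFactors = FALSE)
  elements <- as.data.frame(elements, stringsAsFactors = FALSE)
  if (is.null(constructs$predefined)) constructs$predefined <- FALSE
  constructs$predefined <- as.logical(constructs$predefined)
  ratings <- as.matrix(ratings)
  storage.mode(ratings) <- "integer"
  dimnames(ratings) <- NULL
  rownames(constructs) <- NULL
  rownames(elements) <- NULL
  structure(
    list(constructs = constructs, elements = elements, ratings = ratings),
    class = "repgrid"
  )
}

# returns character vector of problems (empty if valid)
check_repgrid <- function(g) {
  p <- character()
  cs <- g$constructs; el <- g$elements; r <- g$ratings
  if (!all(c("left_pole", "right_pole") %in% names(cs)))
    return("constructs need left_pole and right_pole columns")
  if (!all(c("label", "role") %in% names(el)))
    return("elements need label and role columns")
  if (any(!nzchar(cs$left_pole)) || any(!nzchar(cs$right_pole)))
    p <- c(p, "empty pole label")
  same <- which(cs$left_pole == cs$right_pole)
  if (length(same))
    p <- c(p, sprintf("construct %d has identical poles", same))
  bad_role <- which(!el$role %in% GRID_ROLES)
  if (length(bad_role))
    p <- c(p, sprintf("element %d has unknown role '%s'", bad_role,
                      el$role[bad_role]))
  for (role in c("self_now", "ideal_self")) {
    k <- sum(el$role == role)
    if (k != 1L)
      p <- c(p, sprintf("role %s occurs %d times (must be exactly 1)", role, k))
  }
  if (sum(el$role == "self_year") > 1L)
    p <- c(p, "role self_year occurs more than once (at most 1)")
  if (!identical(dim(r), c(nrow(cs), nrow(el)))) {
    p <- c(p, sprintf("ratings are %d x %d but grid has %d constructs x %d elements",
                      nrow(r), ncol(r), nrow(cs), nrow(el)))
  } else {
    bad <- which(is.na(r) | r < 1L | r > 7L, arr.ind = TRUE)
    if (nrow(bad))
      p <- c(p, sprintf("rating at construct %d, element %d is outside 1..7",
                       bad[, 1], bad[, 2]))
  }
  p
}

#' Construct an implications grid
#'
#' The implications grid records, for each construct, how a hypothetical
#' change from the person's current pole to the opposite pole would move the
#' other constructs, on a signed intensity scale of -3..3. The stored sign
#' convention is right-pole-positive on the target: a positive score means
#' the change pushes the target toward its right pole, a negative score
#' toward its left pole; magnitude 1/2/3 encodes "slightly"/"quite"/"very".
#' The diagonal is fixed at zero.
#'
#' @param constructs data frame of constructs, identical (in order) to the
#'   companion repertory grid's.
#' @param scores n x n integer matrix with entries in -3..3 and zero
#'   diagonal.
#' @return An object of class `impgrid`.
#' @seealso [read_impgrid()], [build_weight_matrix()]
#' @export
impgrid <- function(constructs, scores) {
  constructs <- as.data.frame(constructs, stringsAsFactors = FALSE)
  if (is.null(constructs$predefined)) constructs$predefined <- FALSE
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  dimnames(scores) <- NULL
  rownames(constructs) <- NULL
  g <- structure(list(constructs = constructs, scores = scores),
                 class = "impgrid")
  problems <- check_impgrid(g)
  if (length(problems)) {
    stop("invalid implications grid:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  g
}

check_impgrid <- function(g, grid = NULL) {
  p <- character()
  s <- g$scores
  n <- nrow(g$constructs)
  if (nrow(s) != n || ncol(s) != n) {
    p <- c(p, sprintf("scores are %d x %d but there are %d constructs",
                      nrow(s), ncol(s), n))
    return(p)
  }
  bad <- which(is.na(s) | s < -3L | s > 3L, arr.ind = TRUE)
  if (nrow(bad))
    p <- c(p, sprintf("score at (%d, %d) is outside -3..3", bad[, 1], bad[, 2]))
  nzd <- which(diag(s) != 0L & !is.na(diag(s)))
  if (length(nzd))
    p <- c(p, sprintf("diagonal entry %d is nonzero (a construct cannot imply itself)", nzd))
  if (!is.null(grid)) {
    if (!identical(g$constructs$left_pole, grid$constructs$left_pole) ||
        !identical(g$constructs$right_pole, grid$constructs$right_pole))
      p <- c(p, "construct labels do not match the repertory grid (order matters)")
  }
  p
}

#' @export
print.repgrid <- function(x, ...) {
  n <- nrow(x$constructs); m <- nrow(x$elements)
  cat(sprintf("Repertory grid: %d constructs x %d elements\n", n, m))
  cat(sprintf("  predefined constructs: %d\n", sum(x$constructs$predefined)))
  roles <- x$elements$role
  cat("  elements:", paste0(x$elements$label,
      ifelse(roles == "other", "", paste0(" [", roles, "]")), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.impgrid <- function(x, ...) {
  n <- nrow(x$constructs)
  cat(sprintf("Implications grid: %d x %d, %d nonzero implications\n",
              n, n, sum(x$scores != 0L)))
  invisible(x)
}

role_index <- function(grid, role) {
  i <- which(grid$elements$role == role)
  if (length(i) != 1L)
    stop(sprintf("grid has no unique element with role '%s'", role),
         call. = FALSE)
  i
}

#' Read a repertory grid from CSV or JSON
#'
#' The CSV dialect is: row 1 holds two empty corner cells then the element
#' labels; row 2 two empty corner cells then the element roles
#' (`self_now`/`self_year`/`ideal_self`/`other`); each following row is
#' `left_pole, right_pole`, then the m integer ratings. RFC-4180 quoting,
#' UTF-8. The JSON dialect is the bundled case format produced by
#' [write_case_json()] (the implications part is ignored here).
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"json"`; never auto-detected.
#' @return A validated [repgrid()].
#' @export
read_repgrid <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "json") {
    case <- read_case_json(path, require_implications = FALSE)
    return(case$grid)
  }
  raw <- read.csv(path, header = FALSE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) < 3L)
    stop("repertory grid CSV needs a label row, a role row and at least one construct row",
         call. = FALSE)
  m <- ncol(raw) - 2L
  if (m < 1L) stop("repertory grid CSV has no element columns", call. = FALSE)
  labels <- as.character(raw[1L, -(1:2)])
  roles <- as.character(raw[2L, -(1:2)])
  body <- raw[-(1:2), , drop = FALSE]
  rat <- suppressWarnings(
    matrix(as.numeric(as.matrix(body[, -(1:2), drop = FALSE])),
           nrow = nrow(body))
  )
  bad <- which(is.na(rat) | rat != round(rat), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer rating cell at construct row %d, element column %d",
                 bad[1, 1], bad[1, 2]), call. = FALSE)
  oob <- which(rat < 1 | rat > 7, arr.ind = TRUE)
  if (nrow(oob))
    stop(sprintf("rating %g at construct row %d, element column %d is outside 1..7",
                 rat[oob[1, 1], oob[1, 2]], oob[1, 1], oob[1, 2]),
         call. = FALSE)
  if (!all(roles %in% GRID_ROLES))
    stop("unknown element role token(s): ",
         paste(setdiff(roles, GRID_ROLES), collapse = ", "), call. = FALSE)
  if (sum(roles == "self_now") != 1L || sum(roles == "ideal_self") != 1L)
    stop("the role row must tag exactly one self_now and one ideal_self element",
         call. = FALSE)
  repgrid(
    constructs = data.frame(left_pole = body[[1L]], right_pole = body[[2L]],
                            stringsAsFactors = FALSE),
    elements = data.frame(label = labels, role = roles,
                          stringsAsFactors = FALSE),
    ratings = rat
  )
}

#' Read an implications grid from CSV, aligned with a repertory grid
#'
#' CSV dialect: row 1 is a corner cell followed by the construct left-pole
#' labels; each following row is a construct left-pole label then n integers
#' in -3..3. Row and column construct order must match the companion grid.
#'
#' @param path file to read.
#' @param grid the companion [repgrid()] whose constructs define row/column
#'   order.
#' @return A validated [impgrid()].
#' @export
read_impgrid <- function(path, grid) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(grid, "repgrid"))
  raw <- read.csv(path, header = FALSE, colClasses = "character",
                  check.names = FALSE, fileEncoding = "UTF-8")
  n <- nrow(grid$constructs)
  if (nrow(raw) != n + 1L || ncol(raw) != n + 1L)
    stop(sprintf("implications CSV must be %d x %d (corner + labels); got %d x %d",
                 n + 1L, n + 1L, nrow(raw), ncol(raw)), call. = FALSE)
  col_labels <- as.character(raw[1L, -1L])
  row_labels <- as.character(raw[-1L, 1L])
  want <- grid$constructs$left_pole
  if (!identical(col_labels, want) || !identical(row_labels, want))
    stop("implications grid labels do not align with the repertory grid constructs",
         call. = FALSE)
  s <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw[-1L, -1L, drop = FALSE])), nrow = n)
  )
  if (anyNA(s) || any(s != round(s)))
    stop("implications grid contains non-integer cells", call. = FALSE)
  oob <- which(s < -3 | s > 3, arr.ind = TRUE)
  if (nrow(oob))
    stop(sprintf("implication score %g at (%d, %d) is outside -3..3",
                 s[oob[1, 1], oob[1, 2]], oob[1, 1], oob[1, 2]), call. = FALSE)
  nzd <- which(diag(s) != 0)
  if (length(nzd))
    stop(sprintf("implications grid diagonal must be zero (construct %d implies itself)",
                 nzd[1]), call. = FALSE)
  impgrid(grid$constructs, s)
}

#' Write a repertory grid to CSV or JSON
#'
#' Round-trip guarantee: `read_repgrid(write_repgrid(g, path, d), d)` equals
#' `g` field for field, for both dialects.
#'
#' @param grid a [repgrid()].
#' @param path output file.
#' @param dialect `"csv"` or `"json"`. The JSON dialect writes a bundled
#'   case file with an all-zero implications matrix unless `imp` is given.
#' @param imp optional [impgrid()] to bundle (JSON only).
#' @return `path`, invisibly.
#' @export
write_repgrid <- function(grid, path, dialect = c("csv", "json"), imp = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(grid, "repgrid"))
  if (dialect == "json") {
    if (is.null(imp))
      imp <- impgrid(grid$constructs,
                     matrix(0L, nrow(grid$constructs), nrow(grid$constructs)))
    return(write_case_json(grid, imp, path))
  }
  el <- grid$elements
  header <- rbind(c("", "", el$label), c("", "", el$role))
  body <- cbind(grid$constructs$left_pole, grid$constructs$right_pole,
                matrix(as.character(grid$ratings), nrow = nrow(grid$ratings)))
  tab <- rbind(header, body)
  write.table(tab, path, sep = ",", row.names = FALSE, col.names = FALSE,
              qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an implications grid to CSV
#'
#' @param imp an [impgrid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_impgrid <- function(imp, path) {
  stopifnot(inherits(imp, "impgrid"))
  lab <- imp$constructs$left_pole
  tab <- rbind(c("", lab),
               cbind(lab, matrix(as.character(imp$scores), nrow = length(lab))))
  write.table(tab, path, sep = ",", row.names = FALSE, col.names = FALSE,
              qmethod = "double", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a bundled JSON case (grid + implications)
#'
#' The JSON case is the canonical interchange format:
#' `{"constructs": [...], "elements": [...], "ratings": [[...]],`
#' `"implications": [[...]], "meta": {...}}`.
#'
#' @param grid a [repgrid()].
#' @param imp the companion [impgrid()].
#' @param path file path.
#' @param meta optional named list stored verbatim under `"meta"`.
#' @return `write_case_json()` returns `path` invisibly; `read_case_json()`
#'   returns a list with components `grid`, `imp` (or `NULL`) and `meta`.
#' @export
write_case_json <- function(grid, imp, path, meta = list()) {
  stopifnot(inherits(grid, "repgrid"), inherits(imp, "impgrid"))
  obj <- list(
    constructs = data.frame(left = grid$constructs$left_pole,
                            right = grid$constructs$right_pole,
                            predefined = grid$constructs$predefined,
                            stringsAsFactors = FALSE),
    elements = grid$elements,
    ratings = grid$ratings,
    implications = imp$scores,
    meta = meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_case_json
#' @param require_implications error if the file lacks an implications
#'   matrix.
#' @export
read_case_json <- function(path, require_implications = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (fld in c("constructs", "elements", "ratings"))
    if (is.null(obj[[fld]]))
      stop("JSON case lacks the '", fld, "' field", call. = FALSE)
  grid <- repgrid(
    constructs = data.frame(left_pole = obj$constructs$left,
                            right_pole = obj$constructs$right,
                            predefined = isTRUE_vec(obj$constructs$predefined,
                                                    nrow(obj$constructs)),
                            stringsAsFactors = FALSE),
    elements = as.data.frame(obj$elements, stringsAsFactors = FALSE),
    ratings = obj$ratings
  )
  imp <- NULL
  if (!is.null(obj$implications)) {
    imp <- impgrid(grid$constructs, obj$implications)
  } else if (require_implications) {
    stop("JSON case lacks the 'implications' field", call. = FALSE)
  }
  list(grid = grid, imp = imp, meta = obj$meta)
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) rep(FALSE, n) else as.logical(x)
}

#' Packaged healthy-habits repertory grid template
#'
#' An unscored 12-construct x 11-element template for exploring the meanings
#' a person attaches to weight, eating, physical activity and health. Six
#' constructs are predefined; six are empty slots to be filled during
#' elicitation. Elements cover the Self-Now, a one-year self projection, the
#' Ideal-Self, three significant others, and five comparison roles. All
#' ratings start at the scale midpoint (4).
#'
#' The predefined pole wordings are reconstructions from the construct
#' themes the template is built around (weight, eating control, eating
#' enjoyment, activity, health, confidence); see the package vignette.
#'
#' @return A [repgrid()] with 12 constructs and 11 elements.
#' @export
#' @examples
#' tpl <- healthy_habits_template()
#' nrow(tpl$constructs)             # 12
#' sum(tpl$constructs$predefined)   # 6
healthy_habits_template <- function() {
  constructs <- data.frame(
    left_pole = c("overweight", "uncontrolled eating", "enjoys eating",
                  "active", "healthy", "confident",
                  sprintf("elicited %d left", 1:6)),
    right_pole = c("correct weight", "control of eating",
                   "indifferent to eating", "sedentary", "unhealthy",
                   "insecure",
                   sprintf("elicited %d right", 1:6)),
    predefined = rep(c(TRUE, FALSE), each = 6L),
    stringsAsFactors = FALSE
  )
  elements <- data.frame(
    label = c("Self-Now", "Self-in-a-year", "Ideal-Self", "father", "mother",
              "partner / significant other", "overweight person",
              "not-overweight person", "person with healthy habits",
              "person without healthy habits", "persona non grata"),
    role = c("self_now", "self_year", "ideal_self", rep("other", 8L)),
    stringsAsFactors = FALSE
  )
  repgrid(constructs, elements,
          matrix(4L, nrow(constructs), nrow(elements)))
}

#' Validate a repertory grid / implications grid case
#'
#' Collects every violation (rating and score ranges, role multiplicities,
#' construct alignment, diagonal) instead of stopping at the first, plus
#' warnings for degenerate but legal situations. A case with an empty
#' `violations` list is safe for every downstream operation; in particular,
#' a construct whose Self-Now and Ideal-Self both sit at the midpoint *and*
#' that has nonzero implication scores is reported as a violation, because
#' its hypothesized change direction is undefined.
#'
#' @param grid a [repgrid()] (or a bare list with the same fields;
#'   structural problems are reported, not thrown).
#' @param imp optional [impgrid()] to check against `grid`.
#' @return A list of class `case_validation` with character vectors
#'   `violations` and `warnings`.
#' @export
validate_case <- function(grid, imp = NULL) {
  violations <- check_repgrid(unclass_to_repgrid(grid))
  warnings <- character()
  if (!is.null(imp))
    violations <- c(violations, check_impgrid(imp, grid))
  if (!length(violations)) {
    i_self <- which(grid$elements$role == "self_now")
    i_ideal <- which(grid$elements$role == "ideal_self")
    both_mid <- which(grid$ratings[, i_self] == 4L &
                      grid$ratings[, i_ideal] == 4L)
    for (i in both_mid) {
      msg <- sprintf(
        "construct %d: Self-Now and Ideal-Self both at the midpoint; change direction undefined",
        i)
      if (!is.null(imp) && any(imp$scores[i, ] != 0L)) {
        violations <- c(violations, paste0(
          msg, " but its implication row is nonzero"))
      } else {
        warnings <- c(warnings, msg)
      }
    }
  }
  structure(list(violations = violations, warnings = warnings),
            class = "case_validation")
}

unclass_to_repgrid <- function(g) {
  if (inherits(g, "repgrid")) g
  else new_repgrid(g$constructs, g$elements, g$ratings)
}

#' @export
print.case_validation <- function(x, ...) {
  if (!length(x$violations) && !length(x$warnings)) {
    cat("case is valid (no violations, no warnings)\n")
  } else {
    if (length(x$violations))
      cat("violations:\n", paste0("  - ", x$violations, "\n"), sep = "")
    if (length(x$warnings))
      cat("warnings:\n", paste0("  - ", x$warnings, "\n"), sep = "")
  }
  invisible(x)
}
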