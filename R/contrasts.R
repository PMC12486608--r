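#' Construct a StudyContrast
#'
#' @param studyId,contrastId identifiers; `contrastId` must be unique
#'   within a run.
#' @param peaks data.frame with columns `x`, `y`, `z` (mm) and `space`
#'   (`"MNI"` / `"Talairach"`), in reported order.
#' @param direction `"GM_decrease"` (default) or `"GM_increase"`.
#' @param sexFemaleOnly logical, `NA` when the sample's sex composition is
#'   unknown or mixed information is unavailable.
#' @param ageGroup `"adolescent"`, `"adult"`, `"mixed"` or `"unknown"`.
#' @param clinicalState free text (e.g. `"acute"`, `"recovered"`).
#' @return A [StudyContrast-class].
#' @export
studyContrast <- function(studyId, contrastId, peaks,
                          direction = "GM_decrease",
                          sexFemaleOnly = NA, ageGroup = "unknown",
                          clinicalState = "unknown") {
  peaks <- as.data.frame(peaks)
  if (is.null(peaks$space)) peaks$space <- "MNI"
  new("StudyContrast", studyId = as.character(studyId),
      contrastId = as.character(contrastId),
      peaks = peaks[, c("x", "y", "z", "space")],
      direction = direction, sexFemaleOnly = as.logical(sexFemaleOnly),
      ageGroup = ageGroup, clinicalState = as.character(clinicalState))
}

contrastTableColumns <- c("study", "contrast", "space", "x", "y", "z",
                          "direction", "sex", "age_group", "state")

parseSexFlag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "female_only", "female", "f")] <- TRUE
  out[x %in% c("false", "0", "no", "mixed", "male", "m")] <- FALSE
  out
}

#' Read a study contrast table
#'
#' Parses a delimited text table of published peak coordinates into
#' [StudyContrast-class] objects, one per distinct `(study, contrast)`
#' pair, preserving peak file order. Expected columns:
#' `study, contrast, space, x, y, z, direction, sex, age_group, state`.
#' `space` is `MNI` or `Talairach` per row (Talairach rows keep their
#' label for later conversion); `sex` accepts logical-like values or
#' `female_only` / `mixed`; `age_group` one of
#' `adolescent/adult/mixed/unknown`.
#'
#' @param path CSV (default) or TSV file, UTF-8, decimal point.
#' @param sep field separator; `","` or `"\t"`.
#' @return Named list of [StudyContrast-class] objects, keyed by
#'   contrast id.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("study,contrast,space,x,y,z,direction,sex,age_group,state",
#'              "S1,S1.c1,MNI,10,-20,30,GM_decrease,female_only,adult,acute",
#'              "S1,S1.c1,MNI,-8,14,2,GM_decrease,female_only,adult,acute"),
#'            tf)
#' readContrastTable(tf)
#' @export
readContrastTable <- function(path, sep = ",") {
  if (!file.exists(path)) stop("contrast table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", colClasses = "character")
  if (nrow(tab) == 0L) stop("contrast table is empty: ", path)
  missing <- setdiff(contrastTableColumns, names(tab))
  if (length(missing))
    stop("contrast table is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(v) & !is.na(tab[[cc]]))
    if (length(bad))
      stop(sprintf("non-numeric %s coordinate at line %d: '%s'",
                   cc, bad[1] + 1L, tab[[cc]][bad[1]]))
    if (anyNA(v))
      stop(sprintf("missing %s coordinate at line %d", cc,
                   which(is.na(v))[1] + 1L))
    tab[[cc]] <- v
  }
  badSpace <- which(!tab$space %in% c("MNI", "Talairach"))
  if (length(badSpace))
    stop(sprintf("unknown coordinate space '%s' at line %d",
                 tab$space[badSpace[1]], badSpace[1] + 1L))
  key <- paste(tab$study, tab$contrast, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- tab[key == k, , drop = FALSE]
    sc <- studyContrast(
      studyId = rows$study[1], contrastId = rows$contrast[1],
      peaks = rows[, c("x", "y", "z", "space")],
      direction = rows$direction[1],
      sexFemaleOnly = parseSexFlag(rows$sex[1]),
      ageGroup = rows$age_group[1], clinicalState = rows$state[1])
    out[[sc@contrastId]] <- sc
  }
  if (anyDuplicated(tab$contrast[!duplicated(key)]))
    stop("contrast ids must be unique across studies")
  out
}

#' @rdname readContrastTable
#' @param contrasts list of [StudyContrast-class] objects.
#' @export
writeContrastTable <- function(contrasts, path, sep = ",") {
  rows <- do.call(rbind, lapply(contrasts, function(sc) {
    data.frame(study = sc@studyId, contrast = sc@contrastId,
               space = sc@peaks$space, x = sc@peaks$x, y = sc@peaks$y,
               z = sc@peaks$z, direction = sc@direction,
               sex = ifelse(is.na(sc@sexFemaleOnly), "unknown",
                            ifelse(sc@sexFemaleOnly, "female_only",
                                   "mixed")),
               age_group = sc@ageGroup, state = sc@clinicalState,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Piecewise-affine Talairach<->MNI transform (Brett-style). Both branches
# are a rotation about x by 0.05 rad composed with an anisotropic scaling,
# applied MNI -> Talairach; the z >= 0 branch scales z by 0.92, the z < 0
# branch by 0.84. No translation term, so the origin is a fixed point.
brettMatrix <- function(zScale) {
  a <- 0.05
  rot <- rbind(c(1, 0, 0),
               c(0, cos(a), sin(a)),
               c(0, -sin(a), cos(a)))
  m <- diag(4)
  m[1:3, 1:3] <- rot %*% diag(c(0.99, 0.97, zScale))
  m
}

.brettUp   <- brettMatrix(0.92)  # z >= 0 (above the AC plane)
.brettDown <- brettMatrix(0.84)  # z <  0

#' Convert coordinates between MNI and Talairach space
#'
#' Piecewise-affine transform in the Brett style: a small rotation about
#' the x axis combined with anisotropic scaling, with separate z-scalings
#' above and below the anterior-commissure plane. `mniToTalairach()`
#' selects the branch from the sign of the input MNI z;
#' `talairachToMni()` inverts the z >= 0 branch first and falls back to
#' the z < 0 branch when the candidate's MNI z is negative, which makes
#' the round trip exactly self-consistent away from a thin wedge near the
#' AC plane. `peaksToMni()` converts any Talairach-labelled rows of a
#' contrast's peak table and passes MNI rows through unchanged.
#'
#' The exact published transform the source literature used per study is
#' generally unknowable, so the matrices are pluggable: pass a list with
#' 4x4 elements `up` and `down` to use a different matrix pair.
#'
#' @param xyz length-3 mm coordinate or n-by-3 matrix.
#' @param matrices list with elements `up` and `down` (4x4 MNI->Talairach
#'   matrices); defaults to the classical pair.
#' @return Transformed coordinates, same shape as the input.
#' @examples
#' talairachToMni(c(30, -40, 20))
#' mniToTalairach(talairachToMni(c(30, -40, 20)))
#' @export
mniToTalairach <- function(xyz, matrices = NULL) {
  m <- if (is.null(matrices)) list(up = .brettUp, down = .brettDown)
       else matrices
  xyz <- rbind(xyz)
  out <- xyz
  for (i in seq_len(nrow(xyz))) {
    M <- if (xyz[i, 3] >= 0) m$up else m$down
    out[i, ] <- (M %*% c(xyz[i, ], 1))[1:3]
  }
  if (nrow(out) == 1L) out[1, ] else out
}

#' @rdname mniToTalairach
#' @export
talairachToMni <- function(xyz, matrices = NULL) {
  m <- if (is.null(matrices)) list(up = .brettUp, down = .brettDown)
       else matrices
  xyz <- rbind(xyz)
  out <- xyz
  for (i in seq_len(nrow(xyz))) {
    cand <- solve(m$up, c(xyz[i, ], 1))[1:3]
    if (cand[3] < 0) cand <- solve(m$down, c(xyz[i, ], 1))[1:3]
    out[i, ] <- cand
  }
  if (nrow(out) == 1L) out[1, ] else out
}

#' @rdname mniToTalairach
#' @param contrast a [StudyContrast-class].
#' @export
peaksToMni <- function(contrast, matrices = NULL) {
  pk <- contrast@peaks
  tal <- pk$space == "Talairach"
  if (any(tal)) {
    conv <- talairachToMni(as.matrix(pk[tal, c("x", "y", "z")]),
                           matrices = matrices)
    pk[tal, c("x", "y", "z")] <- rbind(conv)
    pk$space[tal] <- "MNI"
  }
  initialize(contrast, peaks = pk)
}

#' Screen contrast peaks against a gray-matter mask
#'
#' Peaks whose nearest voxel falls outside the mask (or outside the grid)
#' are dropped with a warning; a contrast that loses all of its peaks is
#' excluded from the pipeline, mirroring the study-exclusion rule that
#' removes reports whose coordinates all lie outside the gray-matter mask.
#'
#' @param contrasts list of [StudyContrast-class] objects, peaks already
#'   in MNI space.
#' @param mask a [BrainMask-class] (gray-matter or whole-brain).
#' @return List with `contrasts` (the surviving contrasts, peaks
#'   filtered), `excluded` (character ids of fully-dropped contrasts) and
#'   `report` (data.frame: contrast, kept, dropped, excluded).
#' @export
screenPeaks <- function(contrasts, mask) {
  if (is(contrasts, "StudyContrast")) contrasts <- list(contrasts)
  kept <- list(); excluded <- character()
  rep <- data.frame(contrast = character(), kept = integer(),
                    dropped = integer(), excluded = logical(),
                    stringsAsFactors = FALSE)
  mv <- maskValues(mask)
  for (sc in contrasts) {
    if (any(sc@peaks$space != "MNI"))
      stop("peaks of contrast '", sc@contrastId,
           "' must be converted to MNI before screening")
    xyz <- as.matrix(sc@peaks[, c("x", "y", "z")])
    vox <- rbind(mmToVoxel(xyz, mask@grid))
    inside <- vapply(seq_len(nrow(vox)), function(i) {
      v <- vox[i, ]
      all(v >= 0) && all(v <= mask@grid@dim - 1L) &&
        mv[voxelIndex(v, mask@grid)]
    }, logical(1))
    nDropped <- sum(!inside)
    if (nDropped > 0L)
      warning(sprintf("contrast '%s': dropped %d peak(s) outside the mask",
                      sc@contrastId, nDropped), call. = FALSE)
    if (!any(inside)) {
      excluded <- c(excluded, sc@contrastId)
      rep <- rbind(rep, data.frame(contrast = sc@contrastId, kept = 0L,
                                   dropped = nDropped, excluded = TRUE))
      next
    }
    sc2 <- initialize(sc, peaks = sc@peaks[inside, , drop = FALSE])
    kept[[sc2@contrastId]] <- sc2
    rep <- rbind(rep, data.frame(contrast = sc@contrastId,
                                 kept = sum(inside), dropped = nDropped,
                                 excluded = FALSE))
  }
  list(contrasts = kept, excluded = excluded, report = rep)
}
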