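## Task geometry, category/match logic and behavioral metrics of the delayed
## match-to-spatial-category task.

#' Construct the task geometry
#'
#' Defaults encode the published task layout: 16 base sample positions (four
#' per visual quadrant), discrete per-axis jitter of -0.5/0/+0.5 degrees so
#' that 16 x 3^2 = 144 distinct sample locations exist, a 624-location test
#' grid, a 4-degree boundary shift and a 1.5-degree fixation window. The base
#' x positions are not printed in the source experiment and are a configurable
#' default here; the y = +/-2 rows are the boundary-proximal rows.
#'
#' @param basePositions n x 2 matrix of base sample positions (degrees).
#' @param jitterLevels per-axis jitter offsets (degrees); odd count, symmetric
#'   about 0.
#' @param testPositions m x 2 matrix of test locations; the default is a
#'   24 x 26 rectangular lattice (624 locations) avoiding the meridians and
#'   the shifted boundary ordinates.
#' @param shiftMagnitude boundary shift (degrees).
#' @param fixationRadius fixation window radius (degrees).
#' @return a [TaskGeometry-class] object.
#' @examples
#' geom <- taskGeometry()
#' nrow(enumerateSampleLocations(geom))  # 144
#' @export
taskGeometry <- function(basePositions = NULL,
                         jitterLevels = c(-0.5, 0, 0.5),
                         testPositions = NULL,
                         shiftMagnitude = 4,
                         fixationRadius = 1.5) {
  if (is.null(basePositions)) {
    basePositions <- as.matrix(expand.grid(x = c(-6, -3, 3, 6),
                                           y = c(-5, -2, 2, 5)))
  }
  if (is.null(testPositions)) {
    testPositions <- as.matrix(expand.grid(
      x = c(-rev(seq(0.5, 11.5, by = 1)), seq(0.5, 11.5, by = 1)),
      y = c(-rev(seq(0.5, 12.5, by = 1)), seq(0.5, 12.5, by = 1))))
  }
  dimnames(basePositions) <- list(NULL, c("x", "y"))
  dimnames(testPositions) <- list(NULL, c("x", "y"))
  methods::new("TaskGeometry",
               basePositions = basePositions,
               jitterLevels = as.numeric(jitterLevels),
               testPositions = testPositions,
               shiftMagnitude = shiftMagnitude,
               fixationRadius = fixationRadius)
}

#' Read task geometry from a YAML configuration
#'
#' Reads the `task:` section of a YAML file with keys `base_positions`,
#' `jitter_levels`, `test_positions`, `shift_magnitude`, `fixation_radius`;
#' missing keys fall back to the defaults of [taskGeometry()]. The test grid
#' cardinality is validated at load.
#'
#' @param path YAML file path.
#' @param expectedTestCount expected number of test locations (default 624);
#'   set to `NA` to skip the check.
#' @return a [TaskGeometry-class] object.
#' @export
readTaskConfig <- function(path, expectedTestCount = 624) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML task configs")
  cfg <- yaml::read_yaml(path)$task
  toMat <- function(x) if (is.null(x)) NULL else
    matrix(unlist(x), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
  geom <- taskGeometry(
    basePositions = toMat(cfg$base_positions),
    jitterLevels = if (is.null(cfg$jitter_levels)) c(-0.5, 0, 0.5) else cfg$jitter_levels,
    testPositions = toMat(cfg$test_positions),
    shiftMagnitude = if (is.null(cfg$shift_magnitude)) 4 else cfg$shift_magnitude,
    fixationRadius = if (is.null(cfg$fixation_radius)) 1.5 else cfg$fixation_radius)
  if (!is.na(expectedTestCount) && nrow(geom@testPositions) != expectedTestCount)
    stop("test grid has ", nrow(geom@testPositions), " locations, expected ",
         expectedTestCount)
  geom
}

#' Enumerate all distinct sample locations
#'
#' Cross product of the base positions with the per-axis jitter offsets,
#' de-duplicated. With the default geometry (16 base positions, 3 jitter
#' levels per axis) this yields 144 distinct locations.
#'
#' @param geometry a [TaskGeometry-class].
#' @return numeric matrix (n x 2) of distinct locations.
#' @export
enumerateSampleLocations <- function(geometry) {
  stopifnot(is(geometry, "TaskGeometry"))
  b <- geometry@basePositions
  j <- geometry@jitterLevels
  if (!length(j)) stop("jitterLevels must be non-empty")
  grid <- expand.grid(base = seq_len(nrow(b)), jx = j, jy = j)
  loc <- cbind(x = b[grid$base, 1] + grid$jx, y = b[grid$base, 2] + grid$jy)
  locR <- round(loc, 9)
  dup <- duplicated(locR)
  if (any(dup))
    stop("distinct base positions produce overlapping jittered locations; ",
         "grid misconfigured")
  loc
}

#' Enumerate all sample-test combinations
#'
#' @param geometry a [TaskGeometry-class].
#' @param materialize if `TRUE`, also return the full pair table.
#' @return list with `count` (= n samples x n tests) and, if requested,
#'   `pairs`, a data.frame with columns sampleX, sampleY, testX, testY.
#' @export
enumerateSampleTestPairs <- function(geometry, materialize = FALSE) {
  samples <- enumerateSampleLocations(geometry)
  tests <- geometry@testPositions
  if (!nrow(samples) || !nrow(tests)) stop("empty sample or test grid")
  out <- list(count = nrow(samples) * nrow(tests))
  if (materialize) {
    idx <- expand.grid(s = seq_len(nrow(samples)), t = seq_len(nrow(tests)))
    out$pairs <- data.frame(sampleX = samples[idx$s, 1], sampleY = samples[idx$s, 2],
                            testX = tests[idx$t, 1], testY = tests[idx$t, 2])
  }
  out
}

#' Categorize a location as Above or Below
#'
#' The left hemi-boundary applies for x < 0 and the right one for x > 0;
#' a location is Above iff its y exceeds the applicable boundary (strict).
#' Locations exactly on a meridian or on the applicable boundary are never
#' displayed by the task and raise an error.
#'
#' @param xy numeric vector `c(x, y)` or an n x 2 matrix.
#' @param boundaryYLeft,boundaryYRight hemi-boundary ordinates (degrees).
#' @return character vector of "Above"/"Below".
#' @export
categorizeLocation <- function(xy, boundaryYLeft = 0, boundaryYRight = 0) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  x <- xy[, 1]; y <- xy[, 2]
  if (any(x == 0)) stop("location on the vertical meridian (x = 0) cannot be categorized")
  boundary <- ifelse(x < 0, boundaryYLeft, boundaryYRight)
  if (any(y == boundary)) stop("location lies exactly on the applicable boundary")
  ifelse(y > boundary, "Above", "Below")
}

#' Hemi-boundary positions after a clockwise or counter-clockwise shift
#'
#' A CW shift raises the left hemi-boundary by the shift magnitude and lowers
#' the right one; CCW is the reverse.
#'
#' @param shift "CW" or "CCW" (vectorised).
#' @param magnitude shift magnitude (degrees).
#' @return matrix with columns `left`, `right`.
#' @export
shiftedBoundaries <- function(shift, magnitude = 4) {
  shift <- match.arg(shift, c("CW", "CCW"), several.ok = TRUE)
  s <- ifelse(shift == "CW", 1, -1)
  cbind(left = s * magnitude, right = -s * magnitude)
}

#' Evaluate a sample-test pair for category match
#'
#' The sample is categorized in the original (unshifted) frame and the test in
#' the boundary-shifted frame; a match requires the two categories to agree.
#' The boundary shift never alters the sample's own category.
#'
#' @param sampleXY `c(x, y)` or n x 2 matrix of sample locations.
#' @param shift "CW"/"CCW" per trial.
#' @param testXY `c(x, y)` or n x 2 matrix of test locations.
#' @param geometry a [TaskGeometry-class] (supplies the shift magnitude).
#' @return character vector of "match"/"nonmatch".
#' @export
evaluateMatch <- function(sampleXY, shift, testXY, geometry = taskGeometry()) {
  if (is.null(dim(sampleXY))) sampleXY <- matrix(sampleXY, ncol = 2)
  if (is.null(dim(testXY))) testXY <- matrix(testXY, ncol = 2)
  sampleCat <- categorizeLocation(sampleXY)
  b <- shiftedBoundaries(shift, geometry@shiftMagnitude)
  testCat <- categorizeLocation(testXY, boundaryYLeft = b[, "left"],
                                boundaryYRight = b[, "right"])
  ifelse(sampleCat == testCat, "match", "nonmatch")
}

#' Simulate behavior of a lapsing category-following agent
#'
#' Draws trials with balanced Above/Below, Left/Right and CW/CCW labels,
#' samples uniformly from the jittered sample grid within the drawn category
#' and hemifield, draws the first test uniformly from the test grid with
#' match/nonmatch balanced, and responds by the true match rule except for
#' independent lapses (response flipped with probability `lapseRate`). On a
#' correct nonmatch trial a second test, always a match, follows.
#'
#' @param geometry a [TaskGeometry-class].
#' @param nTrials number of trials (rounded up to a multiple of 8 for exact
#'   balancing).
#' @param lapseRate lapse probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return data.frame with one row per trial: sampleX, sampleY, categoryAB,
#'   hemifieldLR, shift, testX, testY, testMatch, response, correct.
#' @export
simulateBehavior <- function(geometry = taskGeometry(), nTrials = 1000,
                             lapseRate = 0.0723, seed = 1) {
  stopifnot(lapseRate >= 0, lapseRate < 1)
  set.seed(seed)
  nTrials <- 8L * ceiling(nTrials / 8)
  labs <- expand.grid(cat = c("Above", "Below"), hemi = c("Left", "Right"),
                      shift = c("CW", "CCW"), stringsAsFactors = FALSE)
  labs <- labs[rep(seq_len(8), nTrials / 8), ]
  labs <- labs[sample.int(nTrials), ]

  loc <- enumerateSampleLocations(geometry)
  locCat <- categorizeLocation(loc)
  locHemi <- ifelse(loc[, 1] < 0, "Left", "Right")
  sampleIdx <- vapply(seq_len(nTrials), function(i) {
    pool <- which(locCat == labs$cat[i] & locHemi == labs$hemi[i])
    pool[sample.int(length(pool), 1)]
  }, integer(1))
  sampleXY <- loc[sampleIdx, , drop = FALSE]

  ## draw a first test with forced 50/50 match balance
  tests <- geometry@testPositions
  wantMatch <- rep(c(TRUE, FALSE), nTrials / 2)[sample.int(nTrials)]
  b <- shiftedBoundaries(labs$shift, geometry@shiftMagnitude)
  testCatAll <- function(i) categorizeLocation(tests, b[i, "left"], b[i, "right"])
  testIdx <- vapply(seq_len(nTrials), function(i) {
    tc <- testCatAll(i)
    pool <- if (wantMatch[i]) which(tc == labs$cat[i]) else which(tc != labs$cat[i])
    pool[sample.int(length(pool), 1)]
  }, integer(1))
  testXY <- tests[testIdx, , drop = FALSE]
  isMatch <- evaluateMatch(sampleXY, labs$shift, testXY, geometry) == "match"
  stopifnot(all(isMatch == wantMatch))

  lapse <- stats::runif(nTrials) < lapseRate
  response <- ifelse(xor(isMatch, lapse), "Go", "NoGo")
  correct <- (response == "Go") == isMatch
  data.frame(sampleX = sampleXY[, 1], sampleY = sampleXY[, 2],
             categoryAB = labs$cat, hemifieldLR = labs$hemi,
             shift = labs$shift,
             testX = testXY[, 1], testY = testXY[, 2],
             testMatch = isMatch, response = response, correct = correct,
             stringsAsFactors = FALSE)
}

#' Per-location probability of judging the sample Above (and Left)
#'
#' From each trial's first-test response, infer the category judgment the
#' response implies: a Go response asserts that the test matches the sample,
#' so the implied sample category equals the test's (shifted-frame) category;
#' a No-go asserts the opposite. P_ABOVE at a sample location is the fraction
#' of its trials whose implied judgment is "Above"; P_BELOW is returned as the
#' complement, and the same construction along the task-irrelevant dimension
#' gives P_LEFT/P_RIGHT. Locations with zero trials are excluded and flagged.
#'
#' @param behavior trial table as produced by [simulateBehavior()].
#' @param geometry a [TaskGeometry-class].
#' @return data.frame keyed by (sampleX, sampleY) with columns n, pAbove,
#'   pBelow, pLeft, pRight.
#' @export
pAboveMap <- function(behavior, geometry = taskGeometry()) {
  stopifnot(all(c("sampleX", "sampleY", "testX", "testY", "shift",
                  "response") %in% names(behavior)))
  b <- shiftedBoundaries(behavior$shift, geometry@shiftMagnitude)
  testCat <- categorizeLocation(cbind(behavior$testX, behavior$testY),
                                boundaryYLeft = b[, "left"],
                                boundaryYRight = b[, "right"])
  go <- behavior$response == "Go"
  judgedAbove <- (testCat == "Above") == go
  judgedLeft <- ((behavior$testX < 0)) == go
  key <- paste(behavior$sampleX, behavior$sampleY)
  agg <- stats::aggregate(cbind(judgedAbove, judgedLeft),
                          by = list(key = key), FUN = mean)
  n <- as.vector(table(key)[agg$key])
  xy <- do.call(rbind, strsplit(agg$key, " "))
  out <- data.frame(sampleX = as.numeric(xy[, 1]), sampleY = as.numeric(xy[, 2]),
                    n = n, pAbove = agg$judgedAbove, pBelow = 1 - agg$judgedAbove,
                    pLeft = agg$judgedLeft, pRight = 1 - agg$judgedLeft)
  nLoc <- nrow(enumerateSampleLocations(geometry))
  if (nrow(out) < nLoc)
    attr(out, "missingLocations") <- nLoc - nrow(out)
  out[order(out$sampleX, out$sampleY), ]
}

#' Accuracy broken down by a task factor
#'
#' @param behavior trial table with a `correct` column.
#' @param factor one of "eccentricity", "meridian_distance", "hemifield",
#'   "quadrant", "sample_test_distance", "boundary_proximal_flip".
#'   `boundary_proximal_flip` restricts to boundary-proximal samples
#'   (|y| within 0.5 deg of 2) whose retinotopic location changes category
#'   under the trial's boundary shift.
#' @param geometry a [TaskGeometry-class].
#' @return data.frame with columns level, accuracy, n.
#' @export
accuracyBreakdown <- function(behavior, factor, geometry = taskGeometry()) {
  stopifnot("correct" %in% names(behavior))
  x <- behavior$sampleX; y <- behavior$sampleY
  lev <- switch(factor,
    eccentricity = round(sqrt(x^2 + y^2), 1),
    meridian_distance = abs(y),
    hemifield = ifelse(x < 0, "Left", "Right"),
    quadrant = paste0(ifelse(y > 0, "upper-", "lower-"),
                      ifelse(x < 0, "left", "right")),
    sample_test_distance = {
      d <- sqrt((x - behavior$testX)^2 + (y - behavior$testY)^2)
      cut(d, breaks = seq(0, ceiling(max(d) / 4) * 4, by = 4))
    },
    boundary_proximal_flip = {
      keep <- abs(abs(y) - 2) <= 0.5
      b <- shiftedBoundaries(behavior$shift, geometry@shiftMagnitude)
      preCat <- categorizeLocation(cbind(x, y))
      postCat <- categorizeLocation(cbind(x, y), b[, "left"], b[, "right"])
      keep <- keep & (preCat != postCat)
      if (!any(keep)) stop("no boundary-proximal flipped samples in table")
      behavior <- behavior[keep, ]
      ifelse(behavior$sampleY > 0, "Above", "Below")
    },
    stop("unknown factor: ", factor)
  )
  agg <- stats::aggregate(behavior$correct, by = list(level = lev),
                          FUN = function(v) c(mean(v), length(v)))
  data.frame(level = agg$level, accuracy = agg$x[, 1], n = agg$x[, 2])
}
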