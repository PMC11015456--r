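#' Staff wage table
#'
#' Gross hourly wages by role, in EUR/hour. The roles used by the bundled
#' configuration are the five found in a molecular pathology unit:
#' technical secretary operator, technical laboratory operator, biomedical
#' laboratory technician, biologist and physician, but any role names may
#' be used as long as every role referenced by a labor activity is present.
#'
#' @param ... Named hourly wages (EUR/h), or a single named numeric vector
#'   or list.
#' @return A `wage_table` object (named numeric vector).
#' @export
#' @examples
#' wage_table(biologist = 39.24, physician = 60)
wage_table <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.numeric(args[[1L]]) || is.list(args[[1L]]))) {
    args <- as.list(args[[1L]])
  }
  w <- unlist(args)
  if (length(w) == 0L || is.null(names(w)) || any(!nzchar(names(w)))) {
    stop("wage_table() needs named hourly wages", call. = FALSE)
  }
  w <- vapply(w, as.numeric, numeric(1))
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("all hourly wages must be finite and > 0", call. = FALSE)
  }
  structure(w, class = "wage_table")
}

#' @export
print.wage_table <- function(x, ...) {
  cat("Gross hourly wages (EUR/h):\n")
  for (r in names(x)) cat(sprintf("  %-36s %8.2f\n", r, x[[r]]))
  invisible(x)
}

#' A hands-on labor activity
#'
#' One line of hands-on time on one sample: who does it and for how many
#' minutes. Minutes of zero are allowed (the activity then costs nothing).
#'
#' @param role Role name; must exist in the wage table used for costing.
#' @param minutes Hands-on minutes per sample, finite and `>= 0`.
#' @return A `labor_activity` object.
#' @export
labor_activity <- function(role, minutes) {
  stopifnot(is.character(role), length(role) == 1L, nzchar(role))
  if (!is.numeric(minutes) || length(minutes) != 1L ||
      !is.finite(minutes) || minutes < 0) {
    stop("minutes must be a single finite number >= 0", call. = FALSE)
  }
  structure(list(role = role, minutes = as.numeric(minutes)),
            class = "labor_activity")
}

#' Per-sample labor cost
#'
#' Sums `minutes x hourly wage / 60` over all activities. Labor carries no
#' VAT. An empty activity list costs exactly zero.
#'
#' @param activities List of [labor_activity()] objects (possibly empty).
#' @param wages A [wage_table()] covering every role referenced.
#' @return Per-sample labor cost in EUR.
#' @export
#' @examples
#' w <- wage_table(biologist = 30)
#' labor_cost_per_sample(list(labor_activity("biologist", 10)), w)  # 5
labor_cost_per_sample <- function(activities, wages) {
  stopifnot(is.list(activities), inherits(wages, "wage_table"))
  if (length(activities) == 0L) return(0)
  total <- 0
  for (a in activities) {
    if (!inherits(a, "labor_activity")) {
      stop("activities must be labor_activity objects", call. = FALSE)
    }
    if (!a$role %in% names(wages)) {
      stop("wage table has no entry for role '", a$role, "'", call. = FALSE)
    }
    total <- total + a$minutes * unname(wages[[a$role]]) / 60
  }
  total
}

#' Total hands-on minutes by role for a set of activities
#' @param activities List of [labor_activity()] objects.
#' @return Named numeric vector of minutes per role (empty if no activities).
#' @keywords internal
minutes_by_role <- function(activities) {
  if (length(activities) == 0L) return(numeric(0))
  roles <- vapply(activities, function(a) a$role, character(1))
  mins <- vapply(activities, function(a) a$minutes, numeric(1))
  tapply(mins, roles, sum)[unique(roles)]
}
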