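# Ethogram definition and the observation data model.
#
# The scored maternal-behavior repertoire comprises seven mutually exclusive
# states recorded by instantaneous scan sampling every 3 min over a 72-min
# period (25 slots). Six of the seven states serve as nodes of the transition
# network; licking alone (L) is scored but excluded from network construction.

.CODES <- c("HG", "LW", "SUP", "L", "HG/L", "DN", "OFF")
.NODES <- c("HG", "LW", "SUP", "HG/L", "DN", "OFF")
.AUX <- c("NEST_BUILD", "PUP_RETRIEVE", "SELF_GROOM", "PUP_OFF")
.PERIODS <- c("AM", "PM", "DARK")
.GROUPS <- c("CTRL", "LBN")
.N_SLOTS <- 25L
.PPD_MIN <- 2L
.PPD_MAX <- 9L
.OBS_HEADER <- c("dam_id", "group", "ppd", "period", "slot", "code", "aux")

#' Scored maternal-behavior codes
#'
#' The seven mutually exclusive behavior states recorded at each scan sample:
#' high crouch nursing (`HG`), low crouch nursing (`LW`), supine nursing
#' (`SUP`), licking/grooming pups alone (`L`), high crouch combined with
#' licking (`HG/L`), dam in nest not nursing (`DN`), and dam off nest (`OFF`).
#'
#' @return Character vector of the 7 behavior codes, in canonical order.
#' @seealso [network_nodes()] for the 6 codes used as network nodes.
#' @export
#' @examples
#' behavior_codes()
behavior_codes <- function() .CODES

#' Behavior codes used as transition-network nodes
#'
#' All scored codes except `L`: licking alone occurs rarely and almost always
#' in combination with high crouch nursing, where it is scored as the
#' first-class composite code `HG/L`; `L` slots are therefore excluded from
#' network construction (see [transition_matrix()] for the two exclusion
#' policies).
#'
#' @return Character vector of the 6 node codes, in the fixed node order used
#'   by all transition matrices and networks.
#' @export
network_nodes <- function() .NODES

#' Auxiliary (non-state) behavior annotations
#'
#' Event-type behaviors that can co-occur with a scored state: nest building,
#' pup retrieval, dam self-grooming, and pups off nest. They ride on a slot as
#' optional annotations, never enter transition networks, and are analyzable
#' with [response_table()].
#'
#' @return Character vector of the 4 auxiliary event symbols.
#' @export
aux_codes <- function() .AUX

#' Observation periods
#'
#' Three 72-min daily observation periods: two in the light phase (`AM`,
#' `PM`) and one in the dark phase (`DARK`).
#'
#' @return Character vector `c("AM", "PM", "DARK")`.
#' @export
observation_periods <- function() .PERIODS

#' Construct a validated observation dataset
#'
#' An observation dataset is a long table with one row per scan sample: dam,
#' housing group (`CTRL` or `LBN`), postpartum day (2--9), observation period,
#' 0-based slot (0--24), behavior code, and an optional semicolon-joined set of
#' auxiliary annotations. Rows group into sessions of exactly 25 slots per
#' (dam, day, period).
#'
#' @param x A data.frame with columns `dam_id`, `group`, `ppd`, `period`,
#'   `slot`, `code` and optionally `aux`.
#' @param metadata Optional list of free-form provenance (seed, source file,
#'   generation config); stored as an attribute.
#' @return An object of class `beh_dataset` (a data.frame in canonical row
#'   order: dam, day, period, slot).
#' @export
beh_dataset <- function(x, metadata = list()) {
  if (!is.data.frame(x)) stop("`x` must be a data.frame")
  need <- setdiff(.OBS_HEADER, "aux")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"aux" %in% names(x)) x$aux <- ""
  x <- as.data.frame(x)[, .OBS_HEADER]
  x$dam_id <- as.character(x$dam_id)
  x$group <- as.character(x$group)
  x$ppd <- as.integer(x$ppd)
  x$period <- as.character(x$period)
  x$slot <- as.integer(x$slot)
  x$code <- as.character(x$code)
  x$aux <- ifelse(is.na(x$aux), "", as.character(x$aux))
  validate_observations(x)
  ord <- order(x$dam_id, x$ppd, match(x$period, .PERIODS), x$slot)
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  structure(x, metadata = metadata, class = c("beh_dataset", "data.frame"))
}

# Row-level and session-level validation; error messages name offending rows.
validate_observations <- function(x) {
  rowname <- function(i) {
    sprintf("(dam %s, ppd %s, period %s, slot %s)",
            x$dam_id[i], x$ppd[i], x$period[i], x$slot[i])
  }
  bad <- which(!x$code %in% .CODES)
  if (length(bad) > 0)
    stop("unknown behavior code '", x$code[bad[1]], "' at row ", rowname(bad[1]))
  bad <- which(!x$period %in% .PERIODS)
  if (length(bad) > 0)
    stop("unknown period '", x$period[bad[1]], "' at row ", rowname(bad[1]))
  bad <- which(!x$group %in% .GROUPS)
  if (length(bad) > 0)
    stop("unknown group '", x$group[bad[1]], "' at row ", rowname(bad[1]))
  bad <- which(is.na(x$ppd) | x$ppd < .PPD_MIN | x$ppd > .PPD_MAX)
  if (length(bad) > 0)
    stop("postpartum day out of range [", .PPD_MIN, ", ", .PPD_MAX,
         "] at row ", rowname(bad[1]))
  bad <- which(is.na(x$slot) | x$slot < 0L | x$slot >= .N_SLOTS)
  if (length(bad) > 0)
    stop("slot out of range [0, ", .N_SLOTS - 1L, "] at row ", rowname(bad[1]))
  aux_tokens <- strsplit(x$aux[x$aux != ""], ";", fixed = TRUE)
  bad_aux <- setdiff(unique(unlist(aux_tokens)), .AUX)
  if (length(bad_aux) > 0)
    stop("unknown auxiliary event symbol '", bad_aux[1], "'")

  # one group per dam
  gm <- unique(x[, c("dam_id", "group")])
  dup <- gm$dam_id[duplicated(gm$dam_id)]
  if (length(dup) > 0)
    stop("dam '", dup[1], "' appears under more than one group")

  # each session has slots 0..24 exactly once
  key <- paste(x$dam_id, x$ppd, x$period, sep = "\r")
  for (k in unique(key)) {
    slots <- x$slot[key == k]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    where <- sprintf("(dam %s, ppd %s, period %s", parts[1], parts[2], parts[3])
    if (anyDuplicated(slots))
      stop("duplicate observation ", where, ", slot ",
           slots[duplicated(slots)][1], ")")
    missing_slots <- setdiff(seq_len(.N_SLOTS) - 1L, slots)
    if (length(missing_slots) > 0)
      stop("missing observation ", where, ", slot ", missing_slots[1], ")")
  }
  invisible(TRUE)
}

#' @export
print.beh_dataset <- function(x, ...) {
  info <- session_info(x)
  cat("Observation dataset:", nrow(info), "sessions,",
      length(unique(info$dam_id)), "dams\n")
  for (g in intersect(.GROUPS, unique(info$group))) {
    dams <- unique(info$dam_id[info$group == g])
    cat("  ", g, ": ", length(dams), " dams, PPD ",
        min(info$ppd[info$group == g]), "-", max(info$ppd[info$group == g]),
        "\n", sep = "")
  }
  md <- attr(x, "metadata")
  if (!is.null(md$seed)) cat("  simulated (seed ", md$seed, ")\n", sep = "")
  invisible(x)
}

# One row per session, canonical order.
session_info <- function(dataset) {
  unique(as.data.frame(dataset)[, c("dam_id", "group", "ppd", "period")])
}

# 25 x n_sessions character matrix of codes plus the matching session table.
# Relies on the validated canonical row order (slot varies fastest).
session_matrix <- function(dataset) {
  x <- as.data.frame(dataset)
  info <- session_info(dataset)
  m <- matrix(x$code, nrow = .N_SLOTS)
  list(codes = m, info = info)
}

# Codes of one session as a character vector of length 25.
session_codes <- function(dataset, dam_id, ppd, period) {
  x <- as.data.frame(dataset)
  sel <- x$dam_id == dam_id & x$ppd == ppd & x$period == period
  if (!any(sel)) return(NULL)
  x$code[sel][order(x$slot[sel])]
}
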