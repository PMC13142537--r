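#' Built-in proteostasis pathway definitions
#'
#' The four composite scores used along the tau axis:
#' \describe{
#'   \item{proteasome}{PSMA1-7, PSMB1-8, PSME1 and PSMF1 (17 members).}
#'   \item{proteasome_20S}{the catalytic core: PSMA1-7 and PSMB1-8 (15).}
#'   \item{proteasome_19S}{the regulatory particle, resolved at runtime as
#'     all detected IDs matching the PSMC/PSMD prefixes.}
#'   \item{acidification}{11 V-ATPase subunits spanning the V0 and V1
#'     subcomplexes of the lysosomal proton pump.}
#' }
#'
#' @return named list of `pathway_definition` objects; prefix-based
#'   definitions carry `prefixes` instead of a fixed member list.
#' @export
builtin_definitions <- function() {
  def <- function(name, members = NULL, prefixes = NULL) {
    structure(list(name = name, members = members, prefixes = prefixes),
              class = "pathway_definition")
  }
  p20s <- c(sprintf("PSMA%d", 1:7), sprintf("PSMB%d", 1:8))
  acid <- c("ATP6V1G1", "ATP6V1G2", "ATP6V1B2", "ATP6V1C1", "ATP6V1E1",
            "ATP6V1A", "ATP6V0D1", "ATP6V1F", "ATP6V0A1", "ATP6V1H",
            "ATP6V1D")
  list(proteasome = def("proteasome", c(p20s, "PSME1", "PSMF1")),
       proteasome_20S = def("proteasome_20S", p20s),
       proteasome_19S = def("proteasome_19S", prefixes = c("PSMC", "PSMD")),
       acidification = def("acidification", acid))
}

#' Build a pathway definition
#'
#' @param name pathway name.
#' @param members character vector of member protein IDs (unique,
#'   non-empty).
#' @return a `pathway_definition`.
#' @export
pathway_definition <- function(name, members) {
  members <- as.character(members)
  if (!length(members)) stop("pathway '", name, "' has no members")
  if (anyDuplicated(members)) {
    warning("duplicate members in pathway '", name, "' de-duplicated")
    members <- unique(members)
  }
  structure(list(name = name, members = members, prefixes = NULL),
            class = "pathway_definition")
}

# internal: resolve the member IDs of a definition against a matrix
resolve_members <- function(definition, ids) {
  if (!is.null(definition$prefixes)) {
    hit <- rep(FALSE, length(ids))
    for (p in definition$prefixes) hit <- hit | startsWith(ids, p)
    ids[hit]
  } else {
    intersect(definition$members, ids)
  }
}

#' Composite pathway activity score
#'
#' Per-sample score = mean over detected pathway members of the member's
#' z-score (computed per protein across all samples). Absent members are
#' dropped with a message; a definition with no detected member is an
#' error.
#'
#' @param matrix a complete [proteome_matrix()].
#' @param definition a `pathway_definition`.
#' @return named numeric vector, one score per sample; used member IDs are
#'   attached as attribute `members`.
#' @export
pathway_score <- function(matrix, definition) {
  assert_complete(matrix, "pathway_score")
  ids <- rownames(matrix$values)
  members <- resolve_members(definition, ids)
  if (!length(members))
    stop("no member of pathway '", definition$name,
         "' detected in the matrix")
  absent <- if (is.null(definition$prefixes))
    setdiff(definition$members, members) else character()
  if (length(absent))
    message("pathway '", definition$name, "': ", length(absent),
            " member(s) not detected (", paste(absent, collapse = ", "), ")")
  z <- t(scale(t(matrix$values[members, , drop = FALSE])))
  score <- colMeans(z)
  attr(score, "members") <- members
  score
}

#' Mean and SEM of a score per tau bin
#'
#' Summarises a per-sample score within equal-width tau bins from
#' [bin_by_tau()]: per-bin mean, standard error of the mean
#' (sample SD with n - 1 denominator over sqrt(n); `NA` for n = 1) and
#' count. Empty bins are omitted with a warning rather than reported as
#' zero.
#'
#' @param score named numeric vector of per-sample scores.
#' @param bins named integer vector of bin labels from [bin_by_tau()].
#' @return data.frame with columns `bin`, `mean`, `sem`, `n`, one row per
#'   non-empty bin in ascending bin order.
#' @export
binned_trend <- function(score, bins) {
  if (!setequal(names(score), names(bins)))
    stop("score and bins must cover the same samples")
  score <- score[names(bins)]
  lv <- sort(unique(bins))
  out <- do.call(rbind, lapply(lv, function(b) {
    s <- score[bins == b]
    data.frame(bin = b, mean = mean(s),
               sem = if (length(s) > 1) stats::sd(s) / sqrt(length(s))
                     else NA_real_,
               n = length(s))
  }))
  expected <- seq(0L, max(bins))
  missing_bins <- setdiff(expected, lv)
  if (length(missing_bins))
    warning("empty bin(s) omitted: ", paste(missing_bins, collapse = ", "))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
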