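#' Population groups of women aged 15-49
#'
#' The accounting framework partitions women of reproductive age into six
#' population groups: the cross of marital status (married, including
#' cohabiting unions, vs unmarried) and contraceptive-need status (unmet
#' need for contraception, using contraception, or no need). The enumeration
#' is stable: married groups first, and within marital status the order is
#' unmet need, using contraception, no need.
#'
#' Each group maps to exactly one pregnancy-intention source: pregnancies to
#' women with an unmet need or using contraception are unintended-source;
#' pregnancies to women with no contraceptive need are intended-source.
#'
#' @return A data frame with one row per group and columns `group_id`
#'   (integer 1..6), `group` (label `"<marital>.<need>"`), `marital_status`,
#'   `need_status`, and `intention_source` (`"intended"` or `"unintended"`).
#' @examples
#' population_groups()
#' @export
population_groups <- function() {
  marital <- c("married", "unmarried")
  need <- c("unmet_need", "using_contraception", "no_need")
  g <- expand.grid(need_status = need, marital_status = marital,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("marital_status", "need_status")]
  g$group_id <- seq_len(nrow(g))
  g$group <- paste(g$marital_status, g$need_status, sep = ".")
  g$intention_source <- default_intention_map()[g$need_status]
  g[, c("group_id", "group", "marital_status", "need_status",
        "intention_source")]
}

#' Default mapping from contraceptive-need status to intention source
#'
#' Unmet-need and contracepting women are the source of unintended
#' pregnancies (method or user failures, or no method while wanting to avoid
#' pregnancy); women with no contraceptive need are the source of intended
#' pregnancies.
#'
#' @return Named character vector over the three need statuses.
#' @export
default_intention_map <- function() {
  c(unmet_need = "unintended",
    using_contraception = "unintended",
    no_need = "intended")
}

#' Intention source per population group
#'
#' @param intention_map Named character vector mapping each need status to
#'   `"intended"` or `"unintended"`. Defaults to [default_intention_map()].
#' @return Character vector of length 6 (one entry per group, in enumeration
#'   order) with values `"intended"` or `"unintended"`.
#' @export
group_intention <- function(intention_map = default_intention_map()) {
  g <- population_groups()
  need <- unique(g$need_status)
  if (!all(need %in% names(intention_map))) {
    stop("intention map must cover every need status: missing ",
         paste(setdiff(need, names(intention_map)), collapse = ", "))
  }
  bad <- setdiff(unname(intention_map[need]), c("intended", "unintended"))
  if (length(bad)) {
    stop("intention map values must be 'intended' or 'unintended'")
  }
  unname(intention_map[g$need_status])
}

#' Five-year period grid
#'
#' @param from,to First and last period start years.
#' @param width Period width in years.
#' @return Integer vector of period start years (default the six five-year
#'   periods 1990, 1995, ..., 2015 covering 1990-2019).
#' @export
default_periods <- function(from = 1990L, to = 2015L, width = 5L) {
  seq.int(from, to, by = width)
}
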