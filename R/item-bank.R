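#' Construct an item bank of graded-response-model items
#'
#' An item bank holds the polytomous item parameters of one calibrated
#' PROM scale: a positive discrimination (logit slope) `a` and `K - 1`
#' strictly increasing category thresholds per item, all on a common
#' latent z-score scale where higher scores indicate greater symptom
#' severity.
#'
#' @param item_id character vector of unique item identifiers.
#' @param a numeric vector of positive discriminations.
#' @param thresholds list of numeric vectors; element `i` holds the
#'   ordered thresholds `b_1 < ... < b_{K_i - 1}` of item `i`.
#' @param content optional character vector of display text.
#' @param higher_is_worse scale orientation flag: `TRUE` (default) means
#'   a higher latent score represents greater severity.
#' @param validate if `TRUE` (default), stop on an invalid bank.
#'
#' @return An object of class `item_bank`: a list with elements
#'   `item_id`, `content`, `a`, `thresholds` (list), `n_categories`,
#'   and attribute `higher_is_worse`.
#' @examples
#' bank <- item_bank(c("i1", "i2"), a = c(1.8, 2.2),
#'                   thresholds = list(c(-1, 0, 1), c(-0.5, 0.5)))
#' bank
#' @seealso [read_item_bank()], [validate_bank()], [simulate_item_bank()]
#' @export
item_bank <- function(item_id, a, thresholds, content = NULL,
                      higher_is_worse = TRUE, validate = TRUE) {
  item_id <- as.character(item_id)
  n <- length(item_id)
  if (length(a) != n || length(thresholds) != n)
    stop("item_id, a and thresholds must have equal length")
  if (is.null(content)) content <- rep(NA_character_, n)
  thresholds <- lapply(thresholds, as.numeric)
  bank <- structure(
    list(item_id = item_id,
         content = as.character(content),
         a = as.numeric(a),
         thresholds = thresholds,
         n_categories = vapply(thresholds, length, integer(1)) + 1L),
    higher_is_worse = isTRUE(higher_is_worse),
    class = "item_bank")
  if (validate) {
    rep <- validate_bank(bank)
    if (length(rep) > 0L)
      stop("invalid item bank:\n  ", paste(rep, collapse = "\n  "))
  }
  bank
}

#' @export
length.item_bank <- function(x) length(x$item_id)

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %d graded-response items, %s\n", length(x),
              if (attr(x, "higher_is_worse")) "higher = more severe"
              else "higher = less severe"))
  df <- data.frame(item_id = x$item_id, n_categories = x$n_categories,
                   a = round(x$a, 3),
                   thresholds = vapply(x$thresholds, function(b)
                     paste(round(b, 2), collapse = ", "), character(1)))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Validate an item bank
#'
#' Checks every bank invariant and reports all violations rather than
#' stopping at the first: positive discriminations, strictly increasing
#' thresholds, at least two response categories, unique item ids.
#'
#' @param bank an [item_bank()] (or a structurally similar list).
#' @return character vector of human-readable violation messages;
#'   `character(0)` if and only if the bank is valid.
#' @examples
#' b <- item_bank("x", 2, list(c(-1, 1)))
#' validate_bank(b)  # character(0)
#' @export
validate_bank <- function(bank) {
  out <- character(0)
  n <- length(bank$item_id)
  if (n == 0L) return("bank contains no items")
  dup <- unique(bank$item_id[duplicated(bank$item_id)])
  if (length(dup) > 0L)
    out <- c(out, paste0("duplicate item_id: ", paste(dup, collapse = ", ")))
  for (i in seq_len(n)) {
    id <- bank$item_id[i]
    if (!is.finite(bank$a[i]) || bank$a[i] <= 0)
      out <- c(out, paste0(id, ": discrimination not positive (a = ",
                           bank$a[i], ")"))
    b <- bank$thresholds[[i]]
    if (length(b) < 1L)
      out <- c(out, paste0(id, ": fewer than 2 response categories"))
    else if (any(!is.finite(b)))
      out <- c(out, paste0(id, ": non-finite threshold"))
    else if (length(b) > 1L && any(diff(b) <= 0))
      out <- c(out, paste0(id, ": thresholds not strictly increasing"))
  }
  out
}

#' Read an item bank from CSV
#'
#' Expects the interchange layout
#' `item_id,content,n_categories,a,b1,b2,...` (UTF-8, comma-delimited,
#' header row). Items with fewer categories than the widest item leave
#' their trailing threshold columns empty. The reader rejects any bank
#' that fails [validate_bank()].
#'
#' @param path path to the CSV file.
#' @param higher_is_worse scale orientation flag stored on the bank.
#' @return an [item_bank()].
#' @seealso [write_item_bank()]
#' @export
read_item_bank <- function(path, higher_is_worse = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, encoding = "UTF-8")
  need <- c("item_id", "n_categories", "a")
  if (!all(need %in% names(df)))
    stop("item bank CSV must contain columns: ",
         paste(need, collapse = ", "))
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  thresholds <- lapply(seq_len(nrow(df)), function(i) {
    k <- as.integer(df$n_categories[i])
    b <- as.numeric(df[i, bcols, drop = TRUE])
    if (k < 2L || length(bcols) < k - 1L)
      stop("row ", i, " (", df$item_id[i],
           "): n_categories inconsistent with threshold columns")
    extra <- b[-seq_len(k - 1L)]
    if (any(!is.na(extra)))
      stop("row ", i, " (", df$item_id[i],
           "): non-empty threshold beyond n_categories - 1")
    b[seq_len(k - 1L)]
  })
  item_bank(df$item_id,
            a = df$a,
            thresholds = thresholds,
            content = if ("content" %in% names(df)) df$content else NULL,
            higher_is_worse = higher_is_worse)
}

#' Write an item bank to CSV
#'
#' Inverse of [read_item_bank()]; the round trip preserves ids,
#' discriminations and thresholds exactly (to full double precision).
#'
#' @param bank an [item_bank()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  kmax <- max(bank$n_categories)
  mat <- matrix(NA_real_, nrow = length(bank), ncol = kmax - 1L,
                dimnames = list(NULL, paste0("b", seq_len(kmax - 1L))))
  for (i in seq_along(bank$item_id))
    mat[i, seq_along(bank$thresholds[[i]])] <- bank$thresholds[[i]]
  df <- data.frame(item_id = bank$item_id, content = bank$content,
                   n_categories = bank$n_categories, a = bank$a,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(mat))
  utils::write.csv(format_num_df(df), path, row.names = FALSE,
                   quote = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

# full-precision formatting for numeric CSV columns
format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), NA,
                        trimws(formatC(df[[j]], digits = 17,
                                       format = "g")))
  df
}

#' Simulate a synthetic item bank
#'
#' Generates a bank that emulates the structure of an 11-item hand
#' function PROM scored with 7 response categories: discriminations
#' drawn uniformly on `[1.5, 2.5]` and, for each item, equally spaced
#' thresholds centred on a midpoint; midpoints are spread evenly over
#' `[-2, 2]` so the bank is informative across the range of latent
#' severities most patients occupy. This is a synthetic stand-in for a
#' registry-calibrated instrument, not a published calibration.
#'
#' @param n_items number of items (default 11).
#' @param n_categories response categories per item (default 7).
#' @param a_range range of the uniform discrimination draw.
#' @param midpoint_range range over which item threshold midpoints are
#'   spread evenly.
#' @param spacing gap between adjacent thresholds within an item
#'   (default 0.7 logits).
#' @param seed integer seed for the discrimination draw; the default is
#'   the fixed seed used for the bank shipped in `inst/extdata`.
#' @return an [item_bank()] with ids `"item01"`, `"item02"`, ...
#' @examples
#' bank <- simulate_item_bank()
#' length(bank)
#' @export
simulate_item_bank <- function(n_items = 11, n_categories = 7,
                               a_range = c(1.5, 2.5),
                               midpoint_range = c(-2, 2),
                               spacing = 0.7, seed = 20220713) {
  stopifnot(n_items >= 1, n_categories >= 2)
  a <- with_preserved_seed(seed, stats::runif(n_items, a_range[1], a_range[2]))
  mids <- seq(midpoint_range[1], midpoint_range[2], length.out = n_items)
  off <- (seq_len(n_categories - 1) - n_categories / 2) * spacing
  item_bank(sprintf("item%02d", seq_len(n_items)),
            a = a,
            thresholds = lapply(mids, function(m) m + off),
            content = sprintf("synthetic hand-function item %d",
                              seq_len(n_items)))
}

#' The synthetic fixture bank shipped with the package
#'
#' Convenience wrapper returning [simulate_item_bank()] at its defaults;
#' identical to `inst/extdata/synthetic_bank.csv`.
#'
#' @return an [item_bank()] with 11 items and 7 categories each.
#' @export
default_item_bank <- function() simulate_item_bank()

# run expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
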