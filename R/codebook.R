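#' Construct a survey codebook
#'
#' A codebook defines, for every survey item, which response categories exist
#' and how each category is signed: +1 when the answer lines up with the
#' protective knowledge/behaviour expected during the pandemic, -1 when it
#' runs against it, and 0 when it carries no risk information. The ordered
#' set of (item, category) pairs defines the columns of the signed dummy
#' risk matrix.
#'
#' @param items list of item specifications; each element is a list with
#'   fields `item_id` (string), `dimension` (one of `"knowledge"`,
#'   `"perception_severity"`, `"preventive_practice"`), `categories`
#'   (character vector of category labels) and `signs` (integer vector in
#'   \{-1, 0, 1\}, aligned with `categories`).
#' @return An object of class `perceptrisk_codebook` with elements `items`
#'   (the validated specifications) and `dummy_columns` (a data frame with
#'   columns `item_id`, `category`, `sign`, one row per dummy column, in
#'   item order then listed category order).
#' @export
codebook <- function(items) {
  .assert(is.list(items) && length(items) > 0, "`items` must be a non-empty list")
  ids <- vapply(items, function(it) as.character(it$item_id %||% NA_character_),
                character(1))
  .assert(!anyNA(ids) && all(nzchar(ids)), "every item needs an `item_id`")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate item_id in codebook: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  items <- lapply(items, validate_item_coding)
  names(items) <- ids
  dummy <- do.call(rbind, lapply(items, function(it) {
    data.frame(item_id = it$item_id, category = it$categories,
               sign = it$signs, stringsAsFactors = FALSE)
  }))
  rownames(dummy) <- NULL
  structure(list(items = items, dummy_columns = dummy),
            class = "perceptrisk_codebook")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_item_coding <- function(it) {
  .assert(!is.null(it$categories) && length(it$categories) >= 1,
          paste0("item ", it$item_id, ": no categories"))
  it$categories <- as.character(it$categories)
  .assert(!anyDuplicated(it$categories),
          paste0("item ", it$item_id, ": duplicate category labels"))
  dim <- as.character(it$dimension %||% NA_character_)
  if (!dim %in% RISK_DIMENSIONS)
    stop("item ", it$item_id, ": dimension must be one of ",
         paste(RISK_DIMENSIONS, collapse = ", "), call. = FALSE)
  signs <- it$signs
  # signs may be given as a named map or as a vector aligned with categories
  if (!is.null(names(signs)) && all(nzchar(names(signs)))) {
    .assert(setequal(names(signs), it$categories),
            paste0("item ", it$item_id,
                   ": sign map categories do not match `categories`"))
    signs <- signs[it$categories]
  }
  signs <- as.integer(signs)
  .assert(length(signs) == length(it$categories),
          paste0("item ", it$item_id, ": need one sign per category"))
  if (!all(signs %in% c(-1L, 0L, 1L)))
    stop("item ", it$item_id, ": signs must be -1, 0 or +1", call. = FALSE)
  if (all(signs == 0L))
    stop("item ", it$item_id,
         ": all categories map to 0; at least one must be signed",
         call. = FALSE)
  list(item_id = as.character(it$item_id), dimension = dim,
       categories = it$categories, signs = unname(signs))
}

#' Number of dummy columns in a codebook
#' @param cb a `perceptrisk_codebook`
#' @return integer, the total number of (item, category) dummy columns.
#' @export
n_dummy_columns <- function(cb) nrow(cb$dummy_columns)

#' @export
print.perceptrisk_codebook <- function(x, ...) {
  cat("<perceptrisk_codebook>", length(x$items), "items,",
      nrow(x$dummy_columns), "signed dummy columns\n")
  tab <- table(vapply(x$items, `[[`, character(1), "dimension"))
  cat("  dimensions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a codebook from a YAML file
#'
#' The file holds a top-level `items` sequence; each entry has `item_id`,
#' `dimension`, `categories` and `signs` (see [codebook()]). Column order of
#' the resulting risk matrix is a pure function of the file: items in file
#' order, categories in listed order.
#'
#' @param path path to a YAML codebook file
#' @return a `perceptrisk_codebook`
#' @export
load_codebook <- function(path) {
  .assert(file.exists(path), paste0("codebook file not found: ", path))
  doc <- yaml::read_yaml(path)
  .assert(is.list(doc) && !is.null(doc$items),
          "codebook file must contain a top-level `items` list")
  codebook(doc$items)
}

#' Write a codebook to a YAML file
#' @param cb a `perceptrisk_codebook`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  items <- lapply(cb$items, function(it) {
    list(item_id = it$item_id, dimension = it$dimension,
         categories = as.list(it$categories), signs = as.list(it$signs))
  })
  yaml::write_yaml(list(items = unname(items)), path)
  invisible(path)
}

#' Read and validate a respondent table
#'
#' Expects a UTF-8 CSV with one row per respondent: `respondent_id`, `age`,
#' `gender` (female/male), the categorical demographics `civil_status`,
#' `education`, `position`, one column per codebook item (holding a category
#' label, empty/NA for missing), nine 0/1 emotion flags and six 0/1
#' media-use flags (see [emotion_flags()] and [media_flags()]).
#'
#' @param path CSV path
#' @param cb the `perceptrisk_codebook` the responses must conform to
#' @return an object of class `perceptrisk_responses`: a list with
#'   `demographics` (data frame), `items` (character data frame, NA =
#'   missing), `emotions` and `media` (logical data frames), all row-aligned,
#'   plus `respondent_id`.
#' @export
load_responses <- function(path, cb) {
  .assert(file.exists(path), paste0("responses file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  as_responses(raw, cb)
}

#' Coerce a raw respondent data frame into a validated response table
#' @param raw data frame shaped like the CSV described in [load_responses()]
#' @param cb a `perceptrisk_codebook`
#' @return a `perceptrisk_responses`
#' @export
as_responses <- function(raw, cb) {
  demo_cols <- c("respondent_id", "age", "gender", "civil_status",
                 "education", "position")
  item_cols <- names(cb$items)
  need <- c(demo_cols, item_cols, EMOTION_FLAGS, MEDIA_FLAGS)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop("responses table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  id <- as.character(raw$respondent_id)
  dup <- id[duplicated(id)]
  if (length(dup) > 0)
    stop("duplicate respondent_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)

  age <- suppressWarnings(as.integer(raw$age))
  if (nrow(raw) > 0 && anyNA(age))
    stop("unparseable age at row(s): ",
         paste(which(is.na(age)), collapse = ", "), call. = FALSE)
  if (any(age < 15, na.rm = TRUE))
    stop("ages below 15 at row(s): ",
         paste(which(age < 15), collapse = ", "), call. = FALSE)

  gender <- as.character(raw$gender)
  bad_g <- which(!gender %in% c("female", "male"))
  if (nrow(raw) > 0 && length(bad_g) > 0)
    stop("gender must be 'female' or 'male'; offending row(s): ",
         paste(bad_g, collapse = ", "), call. = FALSE)

  items <- raw[item_cols]
  for (j in item_cols) {
    v <- as.character(items[[j]])
    v[!is.na(v) & v == ""] <- NA_character_
    known <- cb$items[[j]]$categories
    bad <- which(!is.na(v) & !v %in% known)
    if (length(bad) > 0)
      stop("item ", j, ": unknown category label(s) ",
           paste(unique(v[bad]), collapse = ", "), " at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    items[[j]] <- v
  }

  parse_flag <- function(col, nm) {
    v <- as.character(col)
    out <- v %in% c("1", "TRUE", "true")
    bad <- which(!v %in% c("0", "1", "TRUE", "FALSE", "true", "false"))
    if (length(bad) > 0)
      stop("flag ", nm, ": values must be 0/1; offending row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    out
  }
  emotions <- as.data.frame(Map(parse_flag, raw[EMOTION_FLAGS], EMOTION_FLAGS),
                            optional = TRUE)
  media <- as.data.frame(Map(parse_flag, raw[MEDIA_FLAGS], MEDIA_FLAGS),
                         optional = TRUE)
  if (nrow(raw) == 0) {  # keep shapes for the header-only case
    emotions <- as.data.frame(matrix(logical(0), 0, length(EMOTION_FLAGS),
                                     dimnames = list(NULL, EMOTION_FLAGS)))
    media <- as.data.frame(matrix(logical(0), 0, length(MEDIA_FLAGS),
                                  dimnames = list(NULL, MEDIA_FLAGS)))
  }

  demographics <- data.frame(respondent_id = id, age = age, gender = gender,
                             civil_status = as.character(raw$civil_status),
                             education = as.character(raw$education),
                             position = as.character(raw$position),
                             stringsAsFactors = FALSE)
  structure(list(respondent_id = id, demographics = demographics,
                 items = items, emotions = emotions, media = media),
            class = "perceptrisk_responses")
}

#' @export
print.perceptrisk_responses <- function(x, ...) {
  cat("<perceptrisk_responses>", length(x$respondent_id), "respondents,",
      ncol(x$items), "items\n")
  invisible(x)
}

#' Number of respondents
#' @param x a `perceptrisk_responses`
#' @return integer count of rows.
#' @export
n_respondents <- function(x) length(x$respondent_id)

#' Canonical emotion / media flag names
#' @return character vector of flag column names.
#' @export
emotion_flags <- function() EMOTION_FLAGS

#' @rdname emotion_flags
#' @export
media_flags <- function() MEDIA_FLAGS

#' Encode responses as a signed dummy risk matrix
#'
#' Each (item, category) pair owns one column; a respondent choosing that
#' category gets the category's sign (-1/0/+1) in that column and 0 in the
#' rest of the item's block, so at most one entry per block is nonzero. A
#' missing response leaves the whole block at zero and therefore contributes
#' nothing to the additive risk score.
#'
#' @param responses a `perceptrisk_responses` validated against `cb`
#' @param cb the `perceptrisk_codebook`
#' @return integer matrix (n respondents x m dummy columns) with values in
#'   \{-1, 0, 1\}; rownames are respondent ids, colnames are
#'   `"item_id=category"`.
#' @export
encode_risk_matrix <- function(responses, cb) {
  .assert(inherits(responses, "perceptrisk_responses"),
          "`responses` must come from load_responses()/as_responses()")
  n <- length(responses$respondent_id)
  dummy <- cb$dummy_columns
  m <- nrow(dummy)
  out <- matrix(0L, n, m,
                dimnames = list(responses$respondent_id,
                                paste(dummy$item_id, dummy$category, sep = "=")))
  col_start <- c(0L, cumsum(vapply(cb$items, function(it)
    length(it$categories), integer(1))))
  for (j in seq_along(cb$items)) {
    it <- cb$items[[j]]
    v <- responses$items[[it$item_id]]
    pick <- match(v, it$categories)          # NA for missing
    chosen <- which(!is.na(pick))
    if (length(chosen) > 0) {
      cols <- col_start[j] + pick[chosen]
      out[cbind(chosen, cols)] <- as.integer(it$signs[pick[chosen]])
    }
  }
  out
}

#' Decode a risk-matrix row block back to category choices
#'
#' Inverse of [encode_risk_matrix()] for signed categories: any nonzero entry
#' identifies the chosen category. Blocks that are entirely zero (missing
#' response, or a chosen zero-signed category) decode to NA.
#'
#' @param matrix a risk matrix from [encode_risk_matrix()]
#' @param cb the codebook used to encode it
#' @return character data frame (n x items) of recovered category labels.
#' @export
decode_risk_matrix <- function(matrix, cb) {
  col_item <- cb$dummy_columns$item_id
  out <- lapply(names(cb$items), function(id) {
    block <- matrix[, col_item == id, drop = FALSE]
    cats <- cb$items[[id]]$categories
    idx <- apply(block != 0L, 1L, function(r) if (any(r)) which(r)[1] else NA_integer_)
    cats[idx]
  })
  names(out) <- names(cb$items)
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
}
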