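#' Variable descriptor table
#'
#' Builds and validates the per-variable metadata used throughout the
#' package: the variable `name`, its `role` in efficiency analysis
#' (`"input"` for provision-side indicators, `"output"` for service
#' utilisation), the main type of care it belongs to (`care_group`:
#' `"R"` residential, `"D"` day, `"O"` outpatient, or `"mixed"`), and the
#' kind of measure (`measure`: `"T"` availability, `"P"` placement
#' capacity, `"Prof"` workforce capacity, `"U"` utilisation). All values
#' are rates per 100,000 inhabitants.
#'
#' Utilisation variables are the outputs and provision variables
#' (availability, placement, workforce) the inputs; the constructor
#' enforces that correspondence.
#'
#' @param name character vector of unique variable identifiers.
#' @param role `"input"` or `"output"`, recycled if length 1.
#' @param care_group one of `"R"`, `"D"`, `"O"`, `"mixed"`.
#' @param measure one of `"T"`, `"P"`, `"Prof"`, `"U"`.
#' @return A `data.frame` with one row per variable.
#' @seealso [parse_variable_descriptors()] for a best-effort parser of
#'   the naming taxonomy.
#' @export
variable_descriptors <- function(name, role, care_group, measure) {
  d <- data.frame(name = as.character(name),
                  role = as.character(role),
                  care_group = as.character(care_group),
                  measure = as.character(measure),
                  stringsAsFactors = FALSE)
  validate_descriptors(d)
  d
}

validate_descriptors <- function(d) {
  req <- c("name", "role", "care_group", "measure")
  if (!all(req %in% names(d)))
    stop("descriptor table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(d$name))
    stop("duplicate variable names in descriptor table: ",
         paste(unique(d$name[duplicated(d$name)]), collapse = ", "))
  if (!all(d$role %in% c("input", "output")))
    stop("role must be 'input' or 'output'")
  if (!all(d$care_group %in% c("R", "D", "O", "mixed")))
    stop("care_group must be one of 'R', 'D', 'O', 'mixed'")
  if (!all(d$measure %in% c("T", "P", "Prof", "U")))
    stop("measure must be one of 'T', 'P', 'Prof', 'U'")
  bad <- (d$role == "output") != (d$measure == "U")
  if (any(bad))
    stop("role/measure mismatch (outputs must be utilisation 'U' ",
         "variables and vice versa): ",
         paste(d$name[bad], collapse = ", "))
  invisible(d)
}

#' Best-effort parser of the variable-naming taxonomy
#'
#' Pre-fills a descriptor table from identifiers following the naming
#' scheme used for care-service indicators: a measure prefix (`T`
#' availability, `P` placement, `Prof` workforce, `U` utilisation)
#' followed by service codes carrying the main type of care (`R`
#' residential, `D` day, `O` outpatient). Names that mix care letters
#' are classified by the first care letter found after the prefix;
#' review the result rather than trusting it blindly, since compound
#' names are not mechanically parseable with certainty.
#'
#' @param names character vector of variable identifiers.
#' @return A descriptor `data.frame` (see [variable_descriptors()]).
#' @export
parse_variable_descriptors <- function(names) {
  measure <- ifelse(grepl("^Prof", names), "Prof",
             ifelse(grepl("^U", names), "U",
             ifelse(grepl("^T", names), "T",
             ifelse(grepl("^P", names), "P", NA))))
  if (anyNA(measure))
    stop("cannot infer measure for: ",
         paste(names[is.na(measure)], collapse = ", "))
  stem <- sub("^(Prof(Psychi|PsychoDUE|Psycho|DUE|Tot)?|U[A-Za-z]*?|T|P)",
              "", names)
  # first care-type letter in the service-code part
  care_group <- vapply(seq_along(names), function(i) {
    m <- regexpr("[RDO][0-9]", stem[i])
    if (m > 0) substr(stem[i], m, m) else "mixed"
  }, character(1))
  role <- ifelse(measure == "U", "output", "input")
  variable_descriptors(names, role, care_group, measure)
}

#' Construct an ecosystem dataset
#'
#' The central data container: a rectangular matrix of non-negative
#' rates (one row per decision-making unit, i.e. small health area, one
#' column per indicator) plus the variable descriptor table. The default
#' study shape is 19 areas by 57 indicators, but any shape is accepted.
#'
#' @param values numeric matrix, rows = DMUs, columns = variables.
#'   Row names (DMU identifiers) and column names are required unless
#'   `dmu_names` is given.
#' @param descriptors descriptor `data.frame`
#'   (see [variable_descriptors()]); its `name` column must match the
#'   matrix columns in order.
#' @param dmu_names optional character vector overriding row names.
#' @return An object of class `ecosystem_dataset` with elements
#'   `dmu_names`, `variables` and `values`.
#' @export
ecosystem_dataset <- function(values, descriptors, dmu_names = NULL) {
  values <- as.matrix(values)
  if (is.null(dmu_names)) dmu_names <- rownames(values)
  if (is.null(dmu_names))
    stop("DMU names are required (row names or dmu_names =)")
  validate_descriptors(descriptors)
  if (ncol(values) != nrow(descriptors))
    stop("matrix has ", ncol(values), " columns but ",
         nrow(descriptors), " descriptors")
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), descriptors$name))
    stop("column names do not match descriptor names (order matters)")
  if (anyDuplicated(dmu_names))
    stop("duplicate DMU names: ",
         paste(unique(dmu_names[duplicated(dmu_names)]), collapse = ", "))
  if (length(dmu_names) != nrow(values))
    stop("length(dmu_names) != nrow(values)")
  neg <- which(values < 0 | is.na(values), arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative or missing value at cell (",
         dmu_names[neg[1, 1]], ", ", descriptors$name[neg[1, 2]], "): ",
         values[neg[1, , drop = FALSE]])
  }
  dimnames(values) <- list(dmu_names, descriptors$name)
  structure(list(dmu_names = dmu_names,
                 variables = descriptors,
                 values = values),
            class = "ecosystem_dataset")
}

#' @export
print.ecosystem_dataset <- function(x, ...) {
  cat("<ecosystem_dataset> ", length(x$dmu_names), " DMUs x ",
      nrow(x$variables), " variables (",
      sum(x$variables$role == "input"), " inputs, ",
      sum(x$variables$role == "output"), " outputs)\n", sep = "")
  invisible(x)
}

#' @export
dim.ecosystem_dataset <- function(x) dim(x$values)

#' Read / write an ecosystem dataset as CSV
#'
#' The CSV dialect is comma-separated UTF-8 with `.` as the decimal
#' separator; the first column holds the DMU name and the header row the
#' variable names. `metadata` is either a descriptor `data.frame`, the
#' path to a descriptor CSV (columns `name`, `role`, `care_group`,
#' `measure`), or `NULL` to infer descriptors from the variable names
#' with [parse_variable_descriptors()].
#'
#' @param path CSV file path.
#' @param metadata descriptor table, path to one, or `NULL`.
#' @return `read_dataset()` returns an `ecosystem_dataset`;
#'   `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path, metadata = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("dataset CSV needs a DMU column plus data columns")
  dmu <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- dmu
  if (anyDuplicated(colnames(vals)))
    stop("duplicate variable names in ", path)
  desc <- if (is.null(metadata)) parse_variable_descriptors(colnames(vals))
          else if (is.character(metadata)) read_descriptors(metadata)
          else metadata
  ecosystem_dataset(vals, desc)
}

#' @rdname read_dataset
#' @param ds an `ecosystem_dataset`.
#' @export
write_dataset <- function(ds, path) {
  df <- data.frame(dmu = ds$dmu_names, ds$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_dataset
#' @export
read_descriptors <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_descriptors(d)
  d
}

#' @rdname read_dataset
#' @param descriptors descriptor table to write.
#' @export
write_descriptors <- function(descriptors, path) {
  utils::write.csv(descriptors, path, row.names = FALSE)
  invisible(path)
}

#' Scenario specifications
#'
#' A scenario is a named, analyst-designed combination of input and
#' output variables giving one "point of view" on efficiency (e.g. day
#' care, outpatient care, workforce capacity). `scenario_spec()` builds
#' one; `load_scenarios()` reads a YAML or JSON file containing a list
#' of scenarios with keys `id`, `label`, `input_vars`, `output_vars`;
#' `default_scenarios()` returns the eleven care-model scenarios shipped
#' with the package (see `inst/extdata/scenarios-care-model.yaml`).
#'
#' @param id short identifier (e.g. `"S4"`).
#' @param label free-text description.
#' @param input_vars,output_vars non-empty character vectors of variable
#'   names; they must not overlap.
#' @param dataset optional `ecosystem_dataset` to validate names and
#'   roles against.
#' @return `scenario_spec()` returns a `scenario_spec` object;
#'   `load_scenarios()` and `default_scenarios()` a named list of them.
#' @export
scenario_spec <- function(id, label, input_vars, output_vars,
                          dataset = NULL) {
  input_vars <- as.character(input_vars)
  output_vars <- as.character(output_vars)
  if (length(input_vars) == 0 || length(output_vars) == 0)
    stop("scenario ", id, ": input_vars and output_vars must be non-empty")
  if (length(intersect(input_vars, output_vars)) > 0)
    stop("scenario ", id, ": a variable cannot be both input and output")
  sc <- structure(list(id = id, label = label,
                       input_vars = input_vars,
                       output_vars = output_vars),
                  class = "scenario_spec")
  if (!is.null(dataset)) validate_scenario(sc, dataset)
  sc
}

#' @rdname scenario_spec
#' @param sc a `scenario_spec`.
#' @export
validate_scenario <- function(sc, dataset) {
  miss <- setdiff(c(sc$input_vars, sc$output_vars),
                  dataset$variables$name)
  if (length(miss) > 0)
    stop("scenario ", sc$id, ": unknown variable(s): ",
         paste(miss, collapse = ", "))
  roles <- setNames(dataset$variables$role, dataset$variables$name)
  wrong_in <- sc$input_vars[roles[sc$input_vars] != "input"]
  wrong_out <- sc$output_vars[roles[sc$output_vars] != "output"]
  if (length(wrong_in) > 0)
    stop("scenario ", sc$id, ": not input-role variables: ",
         paste(wrong_in, collapse = ", "))
  if (length(wrong_out) > 0)
    stop("scenario ", sc$id, ": not output-role variables: ",
         paste(wrong_out, collapse = ", "))
  invisible(sc)
}

#' @rdname scenario_spec
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @export
load_scenarios <- function(path, dataset = NULL) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE,
                                                          simplifyDataFrame = FALSE)
         else yaml::read_yaml(path)
  if (!is.null(raw$scenarios)) raw <- raw$scenarios
  out <- lapply(raw, function(s) {
    scenario_spec(s$id, s$label %||% "",
                  unlist(s$input_vars), unlist(s$output_vars),
                  dataset = dataset)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' @rdname scenario_spec
#' @export
default_scenarios <- function(dataset = NULL) {
  load_scenarios(system.file("extdata", "scenarios-care-model.yaml",
                             package = "rtesim", mustWork = TRUE),
                 dataset = dataset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the input and output sub-matrices for a scenario
#'
#' DMU row order is preserved exactly, so efficiency results stay
#' index-aligned with `ds$dmu_names`.
#'
#' @param ds an `ecosystem_dataset` (or plain matrix with column names).
#' @param sc a `scenario_spec`.
#' @return list with elements `inputs` and `outputs` (numeric matrices).
#' @export
subset_for_scenario <- function(ds, sc) {
  vals <- if (inherits(ds, "ecosystem_dataset")) {
    validate_scenario(sc, ds)
    ds$values
  } else ds
  miss <- setdiff(c(sc$input_vars, sc$output_vars), colnames(vals))
  if (length(miss) > 0)
    stop("scenario ", sc$id, ": unknown variable(s): ",
         paste(miss, collapse = ", "))
  list(inputs = vals[, sc$input_vars, drop = FALSE],
       outputs = vals[, sc$output_vars, drop = FALSE])
}
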