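# make data.table's NSE (:=, .SD) work inside this package
.datatable.aware <- TRUE

#' @importFrom data.table :=
#' @importFrom stats setNames
NULL
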