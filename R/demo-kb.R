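#' Load the bundled demonstration knowledge base
#'
#' Parses the neuropathic-pain knowledge base shipped with the package
#' and attaches its declared inputs and location registry from the
#' bundled config.
#'
#' @param kb_path,config_path Override the bundled files.
#' @return A validated [knowledge_base()].
#' @examples
#' kb <- np_demo_kb()
#' nrow(validate_kb(kb))  # 0: the shipped KB is runnable
#' @export
np_demo_kb <- function(kb_path = system.file("extdata", "neuropathy.kb",
                                             package = "neurocds"),
                       config_path = system.file("extdata", "kb_config.yaml",
                                                 package = "neurocds")) {
  cfg <- read_kb_config(config_path)
  parse_kb_file(kb_path, inputs = cfg$inputs, locations = cfg$locations)
}
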