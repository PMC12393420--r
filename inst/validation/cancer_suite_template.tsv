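# Template for the cancer-literature validation suite. Transcribe one row
# per literature experiment; see parse_validation_suite() for the grammar
# (perturbations: KO:<species>[:<fraction>] or OE:<species>, ';'-separated).
id	perturbation	readout	expected_direction	context	source
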