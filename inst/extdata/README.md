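# Example data

`synthetic_comfort_responses.tsv` — a synthetic bipolar comfort-questionnaire
response sheet (10 participants x 2 devices x 7 lines, marks 1-7), generated
by code; no real participant data. Columns: participant, device, line, mark.
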