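sample	model_type	response
TUM004	patient	responder
TUM006	patient	responder
TUM009	patient	responder
TUM002	patient	responder
H1581	cell_line	responder
DMS114	cell_line	responder
PDX003	pdx	responder
PDX006	pdx	responder
PDX008	pdx	responder
CL001	cell_line	nonresponder
PDX001	pdx	nonresponder
PDX002	pdx	nonresponder
PDX004	pdx	nonresponder
PDX005	pdx	nonresponder
PDX007	pdx	nonresponder
TUM001	patient	nonresponder
TUM003	patient	nonresponder
TUM005	patient	nonresponder
TUM007	patient	nonresponder
TUM008	patient	nonresponder
TUM010	patient	nonresponder
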