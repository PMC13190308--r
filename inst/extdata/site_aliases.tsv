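alias	canonical
lung surgical bed	lung
surgical bed	lung
adrenal	adrenal gland
heart	cardiac
pericardium	cardiac
myocardium	cardiac
stomach	gastric
abdominal wall	soft tissue
subcutaneous	soft tissue
musculoskeletal	soft tissue
bone marrow	bone
mediastinum	mediastinal soft tissue
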