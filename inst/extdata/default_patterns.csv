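pattern,category
small cell lung cancer,sclc
small cell lung ca,sclc
small cell carcinoma,sclc
small cell ca,sclc
small-cell lung cancer,sclc
small-cell lung ca,sclc
small-cell carcinoma,sclc
small-cell ca,sclc
sclc,sclc
oat cell,sclc
non,negation
nsclc,negated_token
lung cancer,lung
lung ca,lung
ca lung,lung
carcinoma of bronchus,lung
bronchial carcinoma,lung
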