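# Default occupation -> (weather exposure, exertion level) mapping.
# Edit and pass via --mapping to reclassify occupations.
preschool_child: {exposure: indoors, exertion: rest}
student: {exposure: indoors, exertion: minimal}
outdoor_play: {exposure: outdoors, exertion: moderate}
office_clerical: {exposure: indoors, exertion: minimal}
retail_services: {exposure: indoors, exertion: minimal}
health_education: {exposure: indoors, exertion: moderate}
manufacturing: {exposure: indoors, exertion: moderate}
construction: {exposure: outdoors, exertion: heavy}
agriculture: {exposure: outdoors, exertion: moderate}
transport: {exposure: outdoors, exertion: minimal}
home_duties: {exposure: indoors, exertion: moderate}
retired: {exposure: indoors, exertion: rest}
not_employed: {exposure: indoors, exertion: rest}
protected: {exposure: not_exposed, exertion: rest}
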