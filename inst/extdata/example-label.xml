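<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic example product label in the supported SPL dialect. -->
<document>
  <id root="SPL-EX-01"/>
  <setId root="SET-EX-01"/>
  <versionNumber value="3"/>
  <title>Examplodone 10mg tablets</title>
  <author><representedOrganization>Example Pharmaceuticals</representedOrganization></author>
  <effectiveTime value="20121025"/>
  <ingredient code="examplodone"/>
  <component><section>
    <code code="SEC-CS"/>
    <text>Efficacy was established in two placebo-controlled trials.</text>
  </section></component>
  <component><section>
    <code code="SEC-DI"/>
    <text>Reported interactions include warfarin at usual doses.</text>
  </section></component>
  <component><section>
    <code code="SEC-CP"/>
    <text>Examplodone is metabolized primarily by CYP2D6.</text>
  </section></component>
</document>
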