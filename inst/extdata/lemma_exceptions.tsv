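# Irregular and non-rule-recoverable English lemma mappings (form<TAB>lemma).
# Covers irregular noun plurals, irregular verb forms, and common regular
# -ed/-ing forms whose base form needs a restored final 'e'.
men	man
women	woman
children	child
feet	foot
teeth	tooth
geese	goose
mice	mouse
lice	louse
people	person
oxen	ox
data	datum
criteria	criterion
phenomena	phenomenon
bacteria	bacterium
media	medium
analyses	analysis
bases	basis
diagnoses	diagnosis
hypotheses	hypothesis
parentheses	parenthesis
prognoses	prognosis
syntheses	synthesis
theses	thesis
crises	crisis
emphases	emphasis
axes	axis
matrices	matrix
indices	index
appendices	appendix
vertices	vertex
leaves	leaf
lives	life
halves	half
knives	knife
loaves	loaf
selves	self
shelves	shelf
wives	wife
wolves	wolf
calves	calf
scarves	scarf
thieves	thief
potatoes	potato
tomatoes	tomato
heroes	hero
echoes	echo
vetoes	veto
series	series
species	species
went	go
gone	go
was	be
were	be
been	be
is	be
are	be
am	be
began	begin
begun	begin
broke	break
broken	break
brought	bring
built	build
bought	buy
came	come
chose	choose
chosen	choose
did	do
done	do
drew	draw
drawn	draw
ate	eat
eaten	eat
fell	fall
fallen	fall
felt	feel
found	find
gave	give
given	give
grew	grow
grown	grow
held	hold
kept	keep
knew	know
known	know
led	lead
left	leave
lost	lose
made	make
meant	mean
met	meet
paid	pay
put	put
ran	run
said	say
saw	see
seen	see
sought	seek
sold	sell
sent	send
showed	show
shown	show
spoke	speak
spoken	speak
spent	spend
stood	stand
took	take
taken	take
taught	teach
thought	think
told	tell
understood	understand
wrote	write
written	write
won	win
achieved	achieve
achieving	achieve
aged	age
aging	age
analyzed	analyze
analyzing	analyze
assessed	assess
associated	associate
associating	associate
based	base
basing	base
calculated	calculate
calculating	calculate
caused	cause
causing	cause
changed	change
changing	change
combined	combine
combining	combine
compared	compare
comparing	compare
completed	complete
completing	complete
conducting	conduct
continued	continue
continuing	continue
created	create
creating	create
decreased	decrease
decreasing	decrease
derived	derive
deriving	derive
described	describe
describing	describe
determined	determine
determining	determine
estimated	estimate
estimating	estimate
evaluated	evaluate
evaluating	evaluate
examined	examine
examining	examine
generated	generate
generating	generate
increased	increase
increasing	increase
included	include
including	include
indicated	indicate
indicating	indicate
involved	involve
involving	involve
measured	measure
measuring	measure
noted	note
noting	note
observed	observe
observing	observe
produced	produce
producing	produce
provided	provide
providing	provide
published	publish
ranged	range
ranging	range
rated	rate
rating	rate
received	receive
receiving	receive
reduced	reduce
reducing	reduce
related	relate
relating	relate
removed	remove
removing	remove
required	require
requiring	require
scored	score
scoring	score
stated	state
stating	state
supplemented	supplement
used	use
using	use
agreed	agree
freed	free
indeed	indeed
hundred	hundred
kindred	kindred
sacred	sacred
controlled	control
controlling	control
modelled	model
modelling	model
travelled	travel
travelling	travel
labelled	label
labelling	label
morning	morning
evening	evening
something	something
nothing	nothing
anything	anything
everything	everything
ceiling	ceiling
lens	lens
lenses	lens
news	news
diabetes	diabetes
viruses	virus
fetuses	fetus
bonuses	bonus
statuses	status
stimuli	stimulus
nuclei	nucleus
fungi	fungus
loci	locus
alumni	alumnus
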